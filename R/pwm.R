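#' Specify a transcription factor motif
#'
#' A TF specification drives the synthetic motif generator. `role_sign`
#' gives the qualitative regulatory role of the TF on each of the four gap
#' genes (+1 activator, -1 repressor, 0 no input); the quantitative weights
#' live in [model_params()]. The repetitive flag marks a low-complexity
#' homopolymer motif (the Hb-like polyA/polyT consensus) whose hits
#' self-overlap on poly-A/T tracts.
#'
#' @param name TF name
#' @param role_sign named numeric vector over the four gap genes
#' @param motif_length motif length in bp (>= 4)
#' @param info_content target information content, bits per column,
#'   strictly inside (0, 2) for a uniform background
#' @param repetitive logical; homopolymer (poly-A) consensus
#' @return object of class `regevo_tf_spec`
#' @export
tf_spec <- function(name, role_sign, motif_length = 8L,
                    info_content = 1.2, repetitive = FALSE) {
  if (motif_length < 4) stop("motif_length must be >= 4")
  if (!all(REGEVO_GENES %in% names(role_sign)))
    stop("role_sign must be defined for every target gene")
  structure(list(name = name, role_sign = role_sign[REGEVO_GENES],
                 motif_length = as.integer(motif_length),
                 info_content = info_content,
                 repetitive = isTRUE(repetitive)),
            class = "regevo_tf_spec")
}

#' Default specifications for the eight gap-gene regulators
#'
#' Bcd and Cad are broad activators (anterior- and posterior-weighted);
#' the four gap proteins cross-repress with the classical mutually
#' exclusive pairs (Hb-Kni, Gt-Kr); Tll and Hkb are terminal repressors.
#' Hb carries the repetitive poly-A consensus.
#'
#' @param info_content target bits per column for all motifs
#' @return named list of `regevo_tf_spec`
#' @export
default_tf_specs <- function(info_content = 1.2) {
  sgn <- default_t_matrix()
  lens <- c(Bcd = 8L, Cad = 8L, Hb = 8L, Gt = 10L, Kr = 9L, Kni = 9L,
            Tll = 8L, Hkb = 7L)
  out <- lapply(REGEVO_TFS, function(tf) {
    tf_spec(tf, role_sign = sign(sgn[tf, ]), motif_length = lens[[tf]],
            info_content = info_content, repetitive = (tf == "Hb"))
  })
  names(out) <- REGEVO_TFS
  out
}

## Per-column information content (uniform background):
## IC(p) = 2 + sum p log2 p. Solve for the dominant-base probability x
## with the other three bases equiprobable.
ic_of_dom <- function(x) {
  rest <- (1 - x) / 3
  2 + x * log2(x) + ifelse(rest > 0, 3 * rest * log2(rest), 0)
}

solve_dom_prob <- function(target_ic) {
  if (target_ic <= 0 || target_ic >= 2)
    stop("info_content per column must lie strictly inside (0, 2) bits ",
         "for a uniform background; requested ", target_ic)
  uniroot(function(x) ic_of_dom(x) - target_ic,
          lower = 0.2500001, upper = 0.9995, tol = 1e-12)$root
}

#' Generate a position weight matrix from a TF specification
#'
#' Columns are drawn independently: a dominant base is chosen (always A
#' for a repetitive spec, giving a homopolymer consensus), the dominant
#' probability is solved so the column information content matches the
#' target (jittered by +/-10% per column, so the realised mean stays
#' within 15% of the target), and log2-odds against the background are
#' stored. The hit threshold is calibrated empirically as the
#' (1 - p_hit) quantile of window scores on an i.i.d. background
#' sequence, i.e. p_hit is the expected chance-hit rate per bp per
#' strand.
#'
#' @param spec a [tf_spec()]
#' @param rng_seed integer seed; the matrix and threshold are pure
#'   functions of (spec, seed)
#' @param background nucleotide background frequencies (A, C, G, T)
#' @param p_hit background tail probability defining the threshold
#' @param n_calib number of background windows used for calibration
#' @return object of class `regevo_pwm`: list with elements `tf`,
#'   `mat` (L x 4 log2-odds, columns A,C,G,T), `threshold`, `repetitive`
#' @export
make_pwm <- function(spec, rng_seed, background = rep(0.25, 4),
                     p_hit = 5e-4, n_calib = 1e5) {
  stopifnot(inherits(spec, "regevo_tf_spec"))
  if (spec$info_content <= 0 || spec$info_content * 1.1 >= 2)
    stop("info_content ", spec$info_content,
         " is infeasible for motif_length ", spec$motif_length,
         ": per-column content must stay inside (0, 2) bits")
  set.seed(rng_seed)
  L <- spec$motif_length
  mat <- matrix(0, L, 4, dimnames = list(NULL, REGEVO_BASES))
  for (j in seq_len(L)) {
    ic_j <- spec$info_content * runif(1, 0.9, 1.1)
    dom <- if (spec$repetitive) 1L else sample.int(4L, 1L)
    x <- solve_dom_prob(ic_j)
    p <- rep((1 - x) / 3, 4)
    p[dom] <- x
    mat[j, ] <- log2(p / background)
  }
  ## threshold: empirical background quantile of window scores
  bg_code <- sample.int(4L, n_calib + L - 1L, replace = TRUE,
                        prob = background)
  sc <- scan_scores_cpp(bg_code, mat)
  thr <- unname(quantile(sc, 1 - p_hit, names = FALSE, type = 7))
  structure(list(tf = spec$name, mat = mat, threshold = thr,
                 p_hit = p_hit, repetitive = spec$repetitive,
                 info_content_target = spec$info_content),
            class = "regevo_pwm")
}

#' Maximum achievable PWM score
#' @param pwm a `regevo_pwm`
#' @return numeric
#' @export
pwm_max_score <- function(pwm) sum(apply(pwm$mat, 1, max))

#' Consensus sequence of a PWM
#' @param pwm a `regevo_pwm`
#' @return character vector of bases, one per column
#' @export
pwm_consensus <- function(pwm) REGEVO_BASES[apply(pwm$mat, 1, which.max)]

#' Realised per-column information content of a PWM
#'
#' Recovers the column distributions from the stored log2-odds and the
#' background, then computes the Kullback-Leibler information per column.
#'
#' @param pwm a `regevo_pwm`
#' @param background background frequencies used to build the matrix
#' @return numeric vector, bits per column
#' @export
pwm_info_content <- function(pwm, background = rep(0.25, 4)) {
  p <- sweep(2^pwm$mat, 2, background, `*`)
  p <- p / rowSums(p)
  rowSums(p * log2(sweep(p, 2, background, `/`)))
}

## Reverse-complement matrix: scanning the forward strand with it scores
## the reverse-strand site occupying the same window.
pwm_rc_matrix <- function(mat) {
  L <- nrow(mat)
  rc <- mat[L:1, 4:1, drop = FALSE]
  colnames(rc) <- REGEVO_BASES
  rc
}

#' Scan a sequence with a PWM on both strands
#'
#' Every window with score >= threshold on either strand is reported,
#' with coordinates on the forward strand, 0-based half-open. Windows
#' containing ambiguous bases are skipped (a message reports how many).
#'
#' @param sequence nucleotide string, or an integer-coded vector
#' @param pwm a `regevo_pwm`
#' @param threshold score cutoff; defaults to the PWM's calibrated
#'   threshold
#' @return data.frame with columns tf, start, length, strand, E
#' @export
scan_pwm <- function(sequence, pwm, threshold = pwm$threshold) {
  code <- if (is.character(sequence)) encode_seq(sequence) else
    as.integer(sequence)
  L <- nrow(pwm$mat)
  if (length(code) < L)
    stop("sequence shorter than motif length")
  n_amb <- sum(is.na(code))
  if (n_amb > 0)
    message(n_amb, " ambiguous base(s); windows covering them skipped")
  h <- scan_hits_cpp(code, pwm$mat, pwm_rc_matrix(pwm$mat), threshold)
  data.frame(tf = rep(pwm$tf, nrow(h)),
             start = as.integer(h[, 1]),
             length = rep(L, nrow(h)),
             strand = c("+", "-")[h[, 2]],
             E = h[, 3],
             stringsAsFactors = FALSE)
}

#' Write / read PWM files
#'
#' Plain-text format, one record per PWM: a header line
#' `>name length threshold` followed by `length` rows of four
#' whitespace-separated log2-odds values (columns A, C, G, T). Values are
#' written at full precision so a round-trip is exact.
#'
#' @param pwms list of `regevo_pwm`
#' @param path file path
#' @return `read_pwms` returns a named list of `regevo_pwm`
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %d %s", p$tf, nrow(p$mat),
                       format(p$threshold, digits = 17)), con)
    writeLines(apply(p$mat, 1, function(r)
      paste(format(r, digits = 17), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_pwms
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], ">"))
      stop("malformed PWM file at line ", i, ": expected '>' header")
    hdr <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1]]
    tf <- hdr[1]
    L <- as.integer(hdr[2])
    thr <- as.numeric(hdr[3])
    rows <- lines[(i + 1):(i + L)]
    mat <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    colnames(mat) <- REGEVO_BASES
    out[[tf]] <- structure(list(tf = tf, mat = mat, threshold = thr,
                                p_hit = NA_real_, repetitive = NA,
                                info_content_target = NA_real_),
                           class = "regevo_pwm")
    i <- i + L + 1L
  }
  out
}

#' Generate the default PWM set
#'
#' One PWM per TF specification, each with its own derived seed.
#'
#' @param specs list of [tf_spec()] (default [default_tf_specs()])
#' @param rng_seed global seed; PWM k uses `derive_seed(rng_seed, k)`
#' @param ... passed to [make_pwm()]
#' @return named list of `regevo_pwm`
#' @export
make_pwm_set <- function(specs = default_tf_specs(), rng_seed = 1, ...) {
  out <- lapply(seq_along(specs), function(k)
    make_pwm(specs[[k]], derive_seed(rng_seed, k), ...))
  names(out) <- vapply(specs, `[[`, "", "name")
  out
}
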