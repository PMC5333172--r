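#' Specify a synthetic regulatory locus
#'
#' @param gene target gap gene name (one of hb, Kr, gt, kni)
#' @param length locus length in bp
#' @param accessible_fraction approximate fraction of the locus covered by
#'   the accessibility (open-chromatin) mask; planted sites are always
#'   covered
#' @param n_planted number of planted binding sites (ignored if
#'   `planted_sites` is given)
#' @param planted_sites optional data.frame(tf, position, tier) of
#'   pre-specified plantings; `tier` is "strong" (consensus) or "weak"
#'   (1-2 mismatches)
#' @return object of class `regevo_locus_spec`
#' @export
locus_spec <- function(gene, length = 2000L, accessible_fraction = 0.8,
                       n_planted = 15L, planted_sites = NULL) {
  stopifnot(length >= 100, accessible_fraction >= 0,
            accessible_fraction <= 1)
  if (!is.null(planted_sites)) {
    stopifnot(all(c("tf", "position", "tier") %in% names(planted_sites)))
    if (any(planted_sites$position < 0 | planted_sites$position >= length))
      stop("planted site positions must lie within [0, length)")
  }
  structure(list(gene = gene, length = as.integer(length),
                 accessible_fraction = accessible_fraction,
                 n_planted = as.integer(n_planted),
                 planted_sites = planted_sites),
            class = "regevo_locus_spec")
}

#' Default four-locus configuration
#'
#' One regulatory locus per gap gene at the desk scale (2 kb each, ~15
#' planted sites, 80% accessible).
#'
#' @inheritParams locus_spec
#' @return named list of `regevo_locus_spec`
#' @export
default_locus_specs <- function(length = 2000L, accessible_fraction = 0.8,
                                n_planted = 15L) {
  out <- lapply(REGEVO_GENES, locus_spec, length = length,
                accessible_fraction = accessible_fraction,
                n_planted = n_planted)
  names(out) <- REGEVO_GENES
  out
}

## Default mixture of TFs among planted sites (per 15 sites): broad
## activator inputs dominate, terminal repressors are sparse.
planted_tf_mix <- function(n) {
  base <- c(Bcd = 3, Cad = 2, Hb = 2, Gt = 2, Kr = 2, Kni = 2,
            Tll = 1, Hkb = 1)
  rep(rep(names(base), base), length.out = n)
}

merge_intervals <- function(start, end) {
  if (length(start) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- integer(0); oute <- integer(0)
  for (k in seq_along(start)[-1]) {
    if (start[k] <= me) me <- max(me, end[k])
    else { outs <- c(outs, ms); oute <- c(oute, me); ms <- start[k]; me <- end[k] }
  }
  data.frame(start = c(outs, ms), end = c(oute, me))
}

## Sequence of a planted site: consensus for "strong", 1-2 second-best
## substitutions for "weak". Repetitive motifs are planted as a longer
## homopolymer run so that scanning yields self-overlapping hits.
planted_site_code <- function(pwm, tier, run_extra = 6L) {
  cons <- apply(pwm$mat, 1, which.max)
  if (isTRUE(pwm$repetitive)) cons <- rep(cons, length.out = nrow(pwm$mat) + run_extra)
  if (tier == "weak" && !isTRUE(pwm$repetitive)) {
    nmm <- sample(1:2, 1)
    pos <- sample(seq_along(cons), nmm)
    for (j in pos) {
      ord <- order(pwm$mat[j, ], decreasing = TRUE)
      cons[j] <- ord[2]
    }
  }
  as.integer(cons)
}

rc_code <- function(code) rev(5L - code)

#' Generate a synthetic genotype
#'
#' Background sequence is i.i.d. over ACGT (optionally GC-biased); planted
#' sites are motif consensus ("strong") or mismatch variants ("weak"),
#' inserted on a random strand at non-overlapping positions. The
#' accessibility mask is a union of intervals that always covers the
#' planted sites; two CRM-like intervals per locus and footprints on a
#' subset of planted sites provide the alternative inclusion routes.
#'
#' @param loci list of [locus_spec()]
#' @param pwms named list of `regevo_pwm` (one per TF)
#' @param rng_seed integer seed; the genotype is a pure function of
#'   (specs, pwms, seed)
#' @param gc GC content of the background (default 0.5, i.e. uniform)
#' @param allow_overlap allow planted sites to overlap each other
#' @param run_extra extra homopolymer bases planted for repetitive motifs
#' @return object of class `regevo_genotype`: integer-coded sequences per
#'   locus plus accessibility / CRM / footprint interval sets (0-based,
#'   half-open) and the planted-site table
#' @export
make_genotype <- function(loci, pwms, rng_seed, gc = 0.5,
                          allow_overlap = FALSE, run_extra = 6L) {
  set.seed(rng_seed)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes <- list(); acc <- list(); crms <- list(); fps <- list()
  planted_all <- list()
  for (ls in loci) {
    len <- ls$length
    code <- sample.int(4L, len, replace = TRUE, prob = probs)
    ## -- decide plantings
    if (is.null(ls$planted_sites)) {
      tfs <- planted_tf_mix(ls$n_planted)
      tiers <- rep(c("strong", "weak"), length.out = ls$n_planted)
      positions <- rep(NA_integer_, ls$n_planted)
    } else {
      tfs <- ls$planted_sites$tf
      tiers <- ls$planted_sites$tier
      positions <- ls$planted_sites$position
    }
    occupied <- logical(len)
    rows <- list()
    for (k in seq_along(tfs)) {
      pwm <- pwms[[tfs[k]]]
      if (is.null(pwm)) stop("no PWM for planted TF ", tfs[k])
      sc <- planted_site_code(pwm, tiers[k], run_extra)
      sl <- length(sc)
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") sc <- rc_code(sc)
      if (is.na(positions[k])) {
        placed <- FALSE
        for (try in 1:500) {
          p <- sample.int(len - sl, 1) - 1L  # 0-based
          win <- (p + 1):(p + sl)
          if (allow_overlap || !any(occupied[win])) {
            positions[k] <- p; placed <- TRUE; break
          }
        }
        if (!placed)
          stop("planted density exceeds locus capacity for gene ", ls$gene)
      } else {
        p <- positions[k]
        if (p + sl > len) stop("planted site extends past locus end")
        win <- (p + 1):(p + sl)
        if (!allow_overlap && any(occupied[win]))
          stop("planted sites overlap at position ", p)
      }
      win <- (positions[k] + 1):(positions[k] + sl)
      occupied[win] <- TRUE
      code[win] <- sc
      rows[[k]] <- data.frame(locus = ls$gene, tf = tfs[k],
                              start = positions[k], length = sl,
                              strand = strand, tier = tiers[k],
                              stringsAsFactors = FALSE)
    }
    planted <- do.call(rbind, rows) %||%
      data.frame(locus = character(0), tf = character(0),
                 start = integer(0), length = integer(0),
                 strand = character(0), tier = character(0))
    ## -- accessibility mask: planted coverage (padded), then random
    ##    intervals until the target fraction is reached
    covered <- logical(len)
    if (nrow(planted) > 0) {
      for (k in seq_len(nrow(planted))) {
        a <- max(0L, planted$start[k] - 20L)
        b <- min(len, planted$start[k] + planted$length[k] + 20L)
        covered[(a + 1):b] <- TRUE
      }
    }
    target <- round(ls$accessible_fraction * len)
    if (ls$accessible_fraction >= 0.999) {
      covered[] <- TRUE
    } else {
      it <- 0
      while (sum(covered) < target && it < 500) {
        w <- sample(150:250, 1)
        s <- sample.int(max(len - w, 1), 1) - 1L
        covered[(s + 1):min(len, s + w)] <- TRUE
        it <- it + 1
      }
    }
    r <- rle(covered)
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    acc_iv <- data.frame(start = s[r$values], end = e[r$values])
    ## -- CRMs: windows centred on planted sites (curated regulatory
    ##    modules sit where the functional sites are), so weak planted
    ##    sites and nearby weak chance sites enter the annotation
    crm_iv <- data.frame(start = integer(0), end = integer(0))
    if (nrow(planted) > 0) {
      pick <- sample.int(nrow(planted), min(2, nrow(planted)))
      crm_iv <- do.call(rbind, lapply(pick, function(i) {
        mid <- planted$start[i] + planted$length[i] %/% 2
        s0 <- max(0L, mid - 100L)
        data.frame(start = s0, end = min(len, s0 + 200L))
      }))
    } else if (nrow(acc_iv) > 0) {
      big <- acc_iv[acc_iv$end - acc_iv$start >= 100, , drop = FALSE]
      if (nrow(big) > 0) {
        pick <- sample.int(nrow(big), min(2, nrow(big)))
        crm_iv <- do.call(rbind, lapply(pick, function(i) {
          w <- min(200L, big$end[i] - big$start[i])
          s0 <- big$start[i] +
            sample.int(max(big$end[i] - big$start[i] - w, 1), 1) - 1L
          data.frame(start = s0, end = s0 + w)
        }))
      }
    }
    ## -- footprints: exact intervals of up to 3 planted sites
    fp_iv <- data.frame(start = integer(0), end = integer(0))
    if (nrow(planted) > 0) {
      pick <- sample.int(nrow(planted), min(3, nrow(planted)))
      fp_iv <- data.frame(start = planted$start[pick],
                          end = planted$start[pick] + planted$length[pick])
    }
    g <- ls$gene
    codes[[g]] <- code
    acc[[g]] <- merge_intervals(acc_iv$start, acc_iv$end)
    crms[[g]] <- merge_intervals(crm_iv$start, crm_iv$end)
    fps[[g]] <- merge_intervals(fp_iv$start, fp_iv$end)
    planted_all[[g]] <- planted
  }
  structure(list(code = codes,
                 loci_lengths = vapply(loci, `[[`, 0L, "length"),
                 accessibility = acc, crms = crms, footprints = fps,
                 planted = do.call(rbind, planted_all),
                 seed = rng_seed),
            class = "regevo_genotype")
}

#' Locus sequences of a genotype as character strings
#' @param genotype a `regevo_genotype`
#' @return named character vector
#' @export
genotype_sequences <- function(genotype) {
  vapply(genotype$code, decode_seq, "")
}

#' Spatial profiles of the external morphogens
#'
#' Concentrations per nucleus along the anterior-posterior row for the
#' four external inputs: Bcd is an anterior-high exponential gradient,
#' Cad its posterior-high mirror, and Tll / Hkb peak at the two terminal
#' nuclei (Hkb more sharply). All values lie in [0, c_max] and the
#' profiles are deterministic functions of the configuration.
#'
#' @param n_nuclei number of nuclei (>= 4)
#' @param c_max maximum concentration (arbitrary units)
#' @param lambda_bcd,lambda_cad,lambda_tll,lambda_hkb decay lengths in
#'   nucleus units; defaults scale with `n_nuclei`
#' @return 4 x n_nuclei matrix, rows Bcd, Cad, Tll, Hkb
#' @export
make_tf_profiles <- function(n_nuclei, c_max = 1,
                             lambda_bcd = n_nuclei / 4,
                             lambda_cad = n_nuclei / 4,
                             lambda_tll = n_nuclei / 12,
                             lambda_hkb = n_nuclei / 20) {
  stopifnot(n_nuclei >= 4)
  i <- 0:(n_nuclei - 1)
  dterm <- pmin(i, n_nuclei - 1 - i)   # distance to nearest pole
  prof <- rbind(
    Bcd = c_max * exp(-i / lambda_bcd),
    Cad = c_max * exp(-(n_nuclei - 1 - i) / lambda_cad),
    Tll = c_max * exp(-dterm / lambda_tll),
    Hkb = c_max * exp(-dterm / lambda_hkb))
  colnames(prof) <- NULL
  prof
}

#' Wild-type expression reference of a genotype
#'
#' Annotates the genotype, runs the expression model, and returns the
#' resulting state as the fitness reference U. By construction the
#' unmutated founder then has rms-score exactly 0 against it.
#'
#' @param genotype a `regevo_genotype`
#' @param pwms PWM set used for annotation
#' @param params [model_params()]
#' @param profiles external TF profiles ([make_tf_profiles()])
#' @param ... passed to [annotate_genotype()]
#' @return an expression state array (see [simulate_expression()])
#' @export
make_wildtype <- function(genotype, pwms, params, profiles, ...) {
  ann <- annotate_genotype(genotype, pwms, ...)
  simulate_expression(ann, params, profiles)
}
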