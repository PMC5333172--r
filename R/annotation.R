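## Internal annotation representation used on the hot path: a numeric
## matrix with columns (tf, locus, start, len, strand, E), tf/locus as
## indices into REGEVO_TFS / the genotype's locus order, strand 1 = '+',
## 2 = '-'. The public API exposes plain data.frames.

ANN_COLS <- c("tf", "locus", "start", "len", "strand", "E")

empty_ann_matrix <- function() {
  m <- matrix(numeric(0), ncol = 6)
  colnames(m) <- ANN_COLS
  m
}

ann_matrix_to_df <- function(m, tf_names = REGEVO_TFS,
                             locus_names = REGEVO_GENES) {
  data.frame(tf = tf_names[m[, "tf"]],
             locus = locus_names[m[, "locus"]],
             start = as.integer(m[, "start"]),
             length = as.integer(m[, "len"]),
             strand = c("+", "-")[m[, "strand"]],
             E = m[, "E"],
             stringsAsFactors = FALSE)
}

ann_df_to_matrix <- function(df, tf_names = REGEVO_TFS,
                             locus_names = REGEVO_GENES) {
  m <- cbind(tf = match(df$tf, tf_names),
             locus = match(df$locus, locus_names),
             start = df$start, len = df$length,
             strand = match(df$strand, c("+", "-")),
             E = df$E)
  colnames(m) <- ANN_COLS
  m
}

sort_ann_matrix <- function(m) {
  m[order(m[, "locus"], m[, "start"], m[, "tf"], m[, "strand"]), ,
    drop = FALSE]
}

## Precompute everything the per-individual annotation step needs:
## PWM matrices (both strands), thresholds, high-score thresholds and
## per-locus interval prefix sums for the three inclusion conditions.
make_annot_ctx <- function(genotype, pwms, high_score_offset = 2,
                           include = TRUE) {
  ## keep TF indices aligned with REGEVO_TFS wherever possible: the
  ## simulation stage indexes concentrations by this order
  if (!is.null(names(pwms)) && all(REGEVO_TFS %in% names(pwms)))
    pwms <- pwms[REGEVO_TFS]
  loci <- names(genotype$code)
  prefix <- function(iv, len) {
    cov <- logical(len)
    if (nrow(iv) > 0)
      for (k in seq_len(nrow(iv)))
        if (iv$end[k] > iv$start[k]) cov[(iv$start[k] + 1):iv$end[k]] <- TRUE
    c(0, cumsum(cov))
  }
  ctx <- list(
    tf_names = vapply(pwms, `[[`, "", "tf"),
    loci = loci,
    mats = lapply(pwms, `[[`, "mat"),
    rcmats = lapply(pwms, function(p) pwm_rc_matrix(p$mat)),
    thr = vapply(pwms, `[[`, 0, "threshold"),
    hst = vapply(pwms, `[[`, 0, "threshold") + high_score_offset,
    include = include)
  if (include) {
    ctx$acc_pref <- lapply(loci, function(g)
      prefix(genotype$accessibility[[g]], genotype$loci_lengths[[g]]))
    ctx$crm_pref <- lapply(loci, function(g)
      prefix(genotype$crms[[g]], genotype$loci_lengths[[g]]))
    ctx$fp_pref <- lapply(loci, function(g)
      prefix(genotype$footprints[[g]], genotype$loci_lengths[[g]]))
    names(ctx$acc_pref) <- names(ctx$crm_pref) <- names(ctx$fp_pref) <- loci
  }
  ctx
}

## Fast annotation of a list of coded locus sequences. Returns the
## internal matrix, sorted by (locus, start).
annotate_code_ <- function(codes, ctx) {
  out <- vector("list", length(codes) * length(ctx$mats))
  z <- 1L
  for (li in seq_along(codes)) {
    code <- codes[[li]]
    for (ti in seq_along(ctx$mats)) {
      h <- scan_hits_cpp(code, ctx$mats[[ti]], ctx$rcmats[[ti]],
                         ctx$thr[[ti]])
      if (nrow(h) == 0) next
      keep <- rep(TRUE, nrow(h))
      if (ctx$include) {
        s <- h[, 1]
        e <- s + nrow(ctx$mats[[ti]])
        ap <- ctx$acc_pref[[li]]; cp <- ctx$crm_pref[[li]]
        fp <- ctx$fp_pref[[li]]
        contained <- (ap[e + 1] - ap[s + 1]) == (e - s)
        cond1 <- (h[, 3] >= ctx$hst[[ti]]) & contained
        cond2 <- (cp[e + 1] - cp[s + 1]) > 0
        cond3 <- (fp[e + 1] - fp[s + 1]) > 0
        keep <- cond1 | cond2 | cond3
      }
      if (!any(keep)) next
      h <- h[keep, , drop = FALSE]
      m <- cbind(tf = ti, locus = li, start = h[, 1],
                 len = nrow(ctx$mats[[ti]]), strand = h[, 2], E = h[, 3])
      out[[z]] <- m
      z <- z + 1L
    }
  }
  out <- out[seq_len(z - 1L)]
  if (length(out) == 0) return(empty_ann_matrix())
  m <- do.call(rbind, out)
  colnames(m) <- ANN_COLS
  sort_ann_matrix(m)
}

#' Annotate a genotype with predicted binding sites
#'
#' Scans every locus with every PWM on both strands and (by default)
#' applies the three inclusion conditions: a site is kept iff it has a
#' high score (threshold + `high_score_offset`) and lies fully inside an
#' accessibility interval, or it overlaps a CRM, or it overlaps a
#' footprint.
#'
#' @param genotype a `regevo_genotype`
#' @param pwms named list of `regevo_pwm`
#' @param include apply the inclusion conditions (set FALSE for raw scan)
#' @param high_score_offset score units above the calibrated threshold
#'   defining a "high" PWM score for inclusion condition (1)
#' @return data.frame(tf, locus, start, length, strand, E) sorted by
#'   (locus, start)
#' @export
annotate_genotype <- function(genotype, pwms, include = TRUE,
                              high_score_offset = 2) {
  ctx <- make_annot_ctx(genotype, pwms, high_score_offset, include)
  m <- annotate_code_(genotype$code, ctx)
  ann_matrix_to_df(m, ctx$tf_names, names(genotype$code))
}

## candidate-interval helpers on merged, sorted, half-open interval sets
interval_contains <- function(iv, s, e) {
  if (nrow(iv) == 0) return(rep(FALSE, length(s)))
  k <- findInterval(s, iv$start)
  ok <- k >= 1
  ok[ok] <- iv$end[k[ok]] >= e[ok] & iv$start[k[ok]] <= s[ok]
  ok
}

interval_overlaps <- function(iv, s, e) {
  if (nrow(iv) == 0) return(rep(FALSE, length(s)))
  k <- findInterval(e - 1, iv$start)
  ok <- k >= 1
  ok[ok] <- iv$end[k[ok]] > s[ok]
  ok
}

#' Apply the three TFBS inclusion conditions
#'
#' A site survives iff (1) its score is at least `high_score_threshold`
#' and its interval is fully contained in an accessibility interval, or
#' (2) it overlaps (>= 1 bp) a CRM interval, or (3) it overlaps a
#' footprint interval. Containment for condition (1) versus overlap for
#' (2)/(3) mirrors "located in" versus "overlapped with". Enlarging any
#' interval set can only keep more sites (monotonicity).
#'
#' @param sites data.frame(tf, locus, start, length, strand, E)
#' @param masks,crms,footprints per-locus interval sets: either a named
#'   list of data.frame(start, end) or a data.frame(locus, start, end);
#'   0-based half-open
#' @param high_score_threshold scalar, or named per-TF vector, of score
#'   cutoffs for condition (1)
#' @return the surviving subset of `sites`
#' @export
apply_inclusion <- function(sites, masks, crms, footprints,
                            high_score_threshold) {
  as_locus_list <- function(x) {
    if (is.data.frame(x)) split(x[c("start", "end")], x$locus) else x
  }
  masks <- as_locus_list(masks); crms <- as_locus_list(crms)
  footprints <- as_locus_list(footprints)
  if (nrow(sites) == 0) return(sites)
  hst <- if (length(high_score_threshold) > 1)
    unname(high_score_threshold[sites$tf]) else
      rep(high_score_threshold, nrow(sites))
  keep <- logical(nrow(sites))
  for (g in unique(sites$locus)) {
    idx <- which(sites$locus == g)
    s <- sites$start[idx]
    e <- s + sites$length[idx]
    merged <- function(set) {
      iv <- set[[g]]
      if (is.null(iv)) data.frame(start = integer(0), end = integer(0))
      else merge_intervals(iv$start, iv$end)
    }
    c1 <- (sites$E[idx] >= hst[idx]) & interval_contains(merged(masks), s, e)
    c2 <- interval_overlaps(merged(crms), s, e)
    c3 <- interval_overlaps(merged(footprints), s, e)
    keep[idx] <- c1 | c2 | c3
  }
  sites[keep, , drop = FALSE]
}

#' Fraction of pairwise site-overlap events
#'
#' An event is an unordered pair of sites on the same locus with
#' intersecting intervals; with `per_tf = TRUE` only same-TF pairs count
#' (self-overlaps) and a per-TF fraction is returned. The fraction is
#' events divided by sites. `method = "sites"` instead counts sites
#' involved in at least one overlap.
#'
#' @param annotation data.frame(tf, locus, start, length, strand, E)
#' @param per_tf logical
#' @param method "pairs" (default) or "sites"
#' @return numeric scalar, or named per-TF vector if `per_tf`
#' @export
overlap_fractions <- function(annotation, per_tf = FALSE,
                              method = c("pairs", "sites")) {
  method <- match.arg(method)
  if (nrow(annotation) == 0) {
    warning("empty annotation: overlap fraction undefined, returning 0")
    return(if (per_tf) setNames(numeric(0), character(0)) else 0)
  }
  count_events <- function(df, same_tf) {
    ev <- 0L
    touched <- rep(FALSE, nrow(df))
    for (g in unique(df$locus)) {
      idx <- which(df$locus == g)
      o <- idx[order(df$start[idx])]
      s <- df$start[o]; e <- s + df$length[o]
      grp <- if (same_tf) match(df$tf[o], unique(df$tf[o])) else
        rep(1L, length(o))
      if (method == "pairs") {
        ev <- ev + sum(overlap_pairs_cpp(as.integer(s), as.integer(e),
                                         as.integer(grp),
                                         max(grp)))
      } else {
        for (i in seq_along(o)) {
          ov <- which(s < e[i] & e > s[i] & grp == grp[i])
          if (length(ov) > 1) touched[o[i]] <- TRUE
        }
      }
    }
    if (method == "pairs") ev else sum(touched)
  }
  if (per_tf) {
    tfs <- unique(annotation$tf)
    out <- vapply(tfs, function(f) {
      sub <- annotation[annotation$tf == f, , drop = FALSE]
      count_events(sub, same_tf = TRUE) / nrow(sub)
    }, 0)
    names(out) <- tfs
    out
  } else {
    count_events(annotation, same_tf = FALSE) / nrow(annotation)
  }
}
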