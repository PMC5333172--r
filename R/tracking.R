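#' Vicinity of a binding site
#'
#' The vicinity is the sequence three times the site length, flanking and
#' containing the site: [start - L, start + 2L), clipped to the locus.
#'
#' @param start 0-based site start
#' @param length site length L
#' @param locus_length locus length for clipping (Inf = no clipping)
#' @return numeric vector c(start, end), half-open
#' @export
vicinity <- function(start, length, locus_length = Inf) {
  c(max(0, start - length), min(locus_length, start + 2 * length))
}

#' Match sites between consecutive generations
#'
#' Event classification for one tracking step: exact coordinate matches
#' (same tf, start, length, strand) persist; remaining old sites are
#' greedily matched, nearest first (ties broken towards smaller
#' coordinates), to unmatched same-TF new sites whose interval overlaps
#' the old site's vicinity - those moved; unmatched old sites died;
#' unmatched new sites are births. Matching is one-to-one, so
#' |old| = persists + moves + deaths and |new| = persists + moves +
#' births.
#'
#' @param sites_g,sites_g1 annotations (data.frames or internal matrices)
#'   at generations g and g+1, same coordinate system
#' @param move_rule "overlap" (default): a candidate's interval must
#'   overlap the vicinity; "start": its start must lie in the vicinity
#' @return list with integer-index components `persist` (two-column
#'   matrix old,new), `moves` (old,new), `deaths` (old), `births` (new)
#' @export
step_match <- function(sites_g, sites_g1, move_rule = c("overlap", "start")) {
  move_rule <- match.arg(move_rule)
  old <- if (is.matrix(sites_g)) sites_g else ann_df_to_matrix(sites_g)
  new <- if (is.matrix(sites_g1)) sites_g1 else ann_df_to_matrix(sites_g1)
  no <- nrow(old); nn <- nrow(new)
  okey <- if (no) site_keys(old) else numeric(0)
  nkey <- if (nn) site_keys(new) else numeric(0)
  hit <- match(okey, nkey)
  persist <- cbind(old = which(!is.na(hit)), new = hit[!is.na(hit)])
  old_free <- which(is.na(hit))
  new_free <- setdiff(seq_len(nn), persist[, "new"])
  moves <- cbind(old = integer(0), new = integer(0))
  if (length(old_free) && length(new_free)) {
    cand <- list(); z <- 1L
    for (oi in old_free) {
      L <- old[oi, "len"]
      v0 <- old[oi, "start"] - L
      v1 <- old[oi, "start"] + 2 * L
      for (ni in new_free) {
        if (new[ni, "tf"] != old[oi, "tf"] ||
            new[ni, "locus"] != old[oi, "locus"]) next
        ok <- if (move_rule == "overlap")
          (new[ni, "start"] + new[ni, "len"]) > v0 && new[ni, "start"] < v1
        else
          new[ni, "start"] >= v0 && new[ni, "start"] < v1
        if (ok) {
          cand[[z]] <- c(oi, ni, abs(new[ni, "start"] - old[oi, "start"]),
                         old[oi, "start"], new[ni, "start"])
          z <- z + 1L
        }
      }
    }
    if (length(cand)) {
      cm <- do.call(rbind, cand)
      cm <- cm[order(cm[, 3], cm[, 4], cm[, 5]), , drop = FALSE]
      used_o <- logical(no); used_n <- logical(nn)
      for (k in seq_len(nrow(cm))) {
        oi <- cm[k, 1]; ni <- cm[k, 2]
        if (!used_o[oi] && !used_n[ni]) {
          moves <- rbind(moves, c(oi, ni))
          used_o[oi] <- TRUE; used_n[ni] <- TRUE
        }
      }
      colnames(moves) <- c("old", "new")
    }
  }
  deaths <- setdiff(old_free, moves[, "old"])
  births <- setdiff(new_free, moves[, "new"])
  storage.mode(moves) <- "integer"
  storage.mode(persist) <- "integer"
  list(persist = persist, moves = moves,
       deaths = as.integer(deaths), births = as.integer(births))
}

#' Classify births as rebirths near dead wild-type sites
#'
#' A birth is a rebirth if the new site's interval overlaps the vicinity
#' of the wild-type (generation 0) coordinates of a same-TF site whose
#' trajectory is currently dead. The nearest such wild-type site is
#' linked; rebirths start new trajectories and do not extend the original
#' trajectory's lifetime.
#'
#' @param births annotation rows (matrix or data.frame) of the born sites
#' @param wildtype wild-type annotation (matrix or data.frame)
#' @param wt_dead logical vector: is each wild-type site's trajectory
#'   currently dead?
#' @return integer vector over births: index of the linked wild-type site
#'   or NA for a plain birth
#' @export
classify_rebirths <- function(births, wildtype, wt_dead) {
  b <- if (is.matrix(births)) births else ann_df_to_matrix(births)
  w <- if (is.matrix(wildtype)) wildtype else ann_df_to_matrix(wildtype)
  out <- rep(NA_integer_, nrow(b))
  if (nrow(b) == 0 || nrow(w) == 0) return(out)
  for (k in seq_len(nrow(b))) {
    cand <- which(wt_dead &
                    w[, "tf"] == b[k, "tf"] &
                    w[, "locus"] == b[k, "locus"])
    if (!length(cand)) next
    L <- w[cand, "len"]
    v0 <- w[cand, "start"] - L
    v1 <- w[cand, "start"] + 2 * L
    ov <- (b[k, "start"] + b[k, "len"]) > v0 & b[k, "start"] < v1
    cand <- cand[ov]
    if (!length(cand)) next
    out[k] <- cand[which.min(abs(w[cand, "start"] - b[k, "start"]))]
  }
  out
}

#' Reconstruct site trajectories across a run
#'
#' Applies [step_match()] to the tracked individual's annotations of
#' consecutive generations, starting from the founder annotation, and
#' classifies births against the wild-type coordinates
#' ([classify_rebirths()]). Deterministic given the recorded tracked
#' stream.
#'
#' @param run a `regevo_run`
#' @param move_rule passed to [step_match()]
#' @return list with `trajectories` (one row per trajectory: id, tf,
#'   locus, origin, origin_gen, death_gen (NA = alive at end), moves,
#'   rebirth_of, origin coordinates and E_wt) and `coords` (long table:
#'   id, gen, start, length, strand, E)
#' @export
track_sites <- function(run, move_rule = "overlap") {
  anns <- lapply(run$records, `[[`, "tracked_annotation")
  G <- length(anns) - 1L
  wt <- anns[[1]]
  ntr <- nrow(wt)
  traj <- list(
    tf = wt[, "tf"], locus = wt[, "locus"],
    origin = rep("initial", ntr), origin_gen = rep(0L, ntr),
    death_gen = rep(NA_integer_, ntr), moves = rep(0L, ntr),
    rebirth_of = rep(NA_integer_, ntr),
    start0 = wt[, "start"], len0 = wt[, "len"], strand0 = wt[, "strand"],
    E_wt = wt[, "E"])
  ## map current annotation row -> trajectory id
  cur_map <- seq_len(ntr)
  coords <- vector("list", G + 1L)
  coords[[1]] <- cbind(id = cur_map, gen = 0L,
                       start = wt[, "start"], length = wt[, "len"],
                       strand = wt[, "strand"], E = wt[, "E"])
  ## wild-type site k corresponds to trajectory k (ids 1..ntr)
  for (g in seq_len(G)) {
    new_ann <- anns[[g + 1L]]
    sm <- step_match(anns[[g]], new_ann, move_rule)
    new_map <- integer(nrow(new_ann))
    if (nrow(sm$persist))
      new_map[sm$persist[, "new"]] <- cur_map[sm$persist[, "old"]]
    if (nrow(sm$moves)) {
      ids <- cur_map[sm$moves[, "old"]]
      new_map[sm$moves[, "new"]] <- ids
      traj$moves[ids] <- traj$moves[ids] + 1L
    }
    if (length(sm$deaths))
      traj$death_gen[cur_map[sm$deaths]] <- g
    if (length(sm$births)) {
      wt_dead <- !is.na(traj$death_gen[seq_len(ntr)])
      reb <- classify_rebirths(new_ann[sm$births, , drop = FALSE], wt,
                               wt_dead)
      for (k in seq_along(sm$births)) {
        ni <- sm$births[k]
        id <- length(traj$tf) + 1L
        traj$tf <- c(traj$tf, new_ann[ni, "tf"])
        traj$locus <- c(traj$locus, new_ann[ni, "locus"])
        traj$origin <- c(traj$origin,
                         if (is.na(reb[k])) "born" else "rebirth")
        traj$origin_gen <- c(traj$origin_gen, g)
        traj$death_gen <- c(traj$death_gen, NA_integer_)
        traj$moves <- c(traj$moves, 0L)
        traj$rebirth_of <- c(traj$rebirth_of, reb[k])
        traj$start0 <- c(traj$start0, new_ann[ni, "start"])
        traj$len0 <- c(traj$len0, new_ann[ni, "len"])
        traj$strand0 <- c(traj$strand0, new_ann[ni, "strand"])
        traj$E_wt <- c(traj$E_wt, new_ann[ni, "E"])
        new_map[ni] <- id
      }
    }
    cur_map <- new_map
    if (nrow(new_ann))
      coords[[g + 1L]] <- cbind(id = cur_map, gen = g,
                                start = new_ann[, "start"],
                                length = new_ann[, "len"],
                                strand = new_ann[, "strand"],
                                E = new_ann[, "E"])
  }
  trajectories <- data.frame(
    id = seq_along(traj$tf), tf = REGEVO_TFS[traj$tf],
    locus = run$loci[traj$locus], origin = traj$origin,
    origin_gen = traj$origin_gen, death_gen = traj$death_gen,
    moves = traj$moves, rebirth_of = traj$rebirth_of,
    start0 = as.integer(traj$start0), length0 = as.integer(traj$len0),
    strand0 = c("+", "-")[traj$strand0], E_wt = traj$E_wt,
    stringsAsFactors = FALSE)
  coords <- as.data.frame(do.call(rbind, coords))
  structure(list(trajectories = trajectories, coords = coords, G = G,
                 n_initial = ntr),
            class = "regevo_tracks")
}

#' Trajectory lifetimes
#'
#' Lifetime = death generation - origin generation. Trajectories alive at
#' the end of the run are right-censored at G and flagged.
#'
#' @param tracks a `regevo_tracks` (or its `trajectories` data.frame,
#'   with G supplied)
#' @param G number of generations (taken from `tracks` if available)
#' @return data.frame(id, lifetime, censored)
#' @export
lifetimes <- function(tracks, G = NULL) {
  tr <- if (inherits(tracks, "regevo_tracks")) tracks$trajectories else tracks
  G <- G %||% tracks$G
  cens <- is.na(tr$death_gen)
  lt <- ifelse(cens, G - tr$origin_gen, tr$death_gen - tr$origin_gen)
  data.frame(id = tr$id, lifetime = as.integer(lt), censored = cens)
}

#' Core binding sites
#'
#' Trajectories originating in the founder and alive in every generation
#' of the run (moves allowed). The `identical_coords` flag additionally
#' reports which core sites kept identical coordinates throughout.
#'
#' @param tracks a `regevo_tracks`
#' @param G number of generations (taken from `tracks` if NULL)
#' @return data.frame of core trajectories with the `identical_coords`
#'   flag
#' @export
core_sites <- function(tracks, G = NULL) {
  G <- G %||% tracks$G
  tr <- tracks$trajectories
  core <- tr[tr$origin == "initial" & is.na(tr$death_gen), , drop = FALSE]
  if (nrow(core)) {
    ic <- vapply(core$id, function(i) {
      cc <- tracks$coords[tracks$coords$id == i, , drop = FALSE]
      nrow(cc) == G + 1L && length(unique(cc$start)) == 1L &&
        length(unique(cc$strand)) == 1L
    }, TRUE)
    core$identical_coords <- ic
  } else core$identical_coords <- logical(0)
  core
}

#' Classify non-core trajectories relative to the core sites
#'
#' Using origin (first-recorded) coordinates: a non-core trajectory is
#' "cooperative" if it is a same-TF site within `coop_range` bp
#' (edge-to-edge) of at least one core site; "overlapping" if its
#' interval intersects any core site and it is not cooperative
#' (cooperative takes precedence); otherwise "other".
#'
#' @param tracks a `regevo_tracks`
#' @param coop_range cooperativity distance, bp
#' @return data.frame(id, class) over non-core trajectories
#' @export
classify_neighbors <- function(tracks, coop_range = 50) {
  tr <- tracks$trajectories
  core <- core_sites(tracks)
  non <- tr[!(tr$id %in% core$id), , drop = FALSE]
  if (nrow(non) == 0)
    return(data.frame(id = integer(0), class = character(0)))
  cls <- vapply(seq_len(nrow(non)), function(k) {
    s <- non$start0[k]; e <- s + non$length0[k]
    same <- core[core$locus == non$locus[k], , drop = FALSE]
    if (nrow(same) == 0) return("other")
    cs <- same$start0; ce <- cs + same$length0
    gap <- pmax(cs - e, s - ce)        # negative when overlapping
    coop <- any(same$tf == non$tf[k] & gap <= coop_range)
    if (coop) return("cooperative")
    if (any(gap < 0)) return("overlapping")
    "other"
  }, "")
  data.frame(id = non$id, class = cls, stringsAsFactors = FALSE)
}
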