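## Hand-constructed annotations make every event type explicit. A "run"
## here is just a sequence of tracked annotations (fake_run).

test_that("vicinity is three site lengths, centred, clipped at locus bounds", {
  expect_identical(vicinity(100, 10), c(90, 120))
  expect_identical(vicinity(0, 10, locus_length = 500), c(0, 20))
  expect_identical(vicinity(495, 10, locus_length = 500), c(485, 500))
  v <- vicinity(300, 7)
  expect_identical(diff(v), 21)      # 3L when unclipped
})

test_that("identical annotations give all persists", {
  a <- ann_df(c("Bcd", "Hb"), "hb", c(10, 50), 8)
  sm <- step_match(a, a)
  expect_identical(nrow(sm$persist), 2L)
  expect_identical(nrow(sm$moves), 0L)
  expect_length(sm$deaths, 0)
  expect_length(sm$births, 0)
})

test_that("a same-TF site inside the vicinity is a move; outside is death plus birth", {
  old <- ann_df("Bcd", "hb", 100, 10)
  inside <- ann_df("Bcd", "hb", 110, 10)     # [110,120) overlaps [90,120)
  sm <- step_match(old, inside)
  expect_identical(nrow(sm$moves), 1L)
  expect_length(sm$deaths, 0)
  outside <- ann_df("Bcd", "hb", 150, 10)    # interval [150,160) misses [90,130)
  sm2 <- step_match(old, outside)
  expect_length(sm2$deaths, 1)
  expect_length(sm2$births, 1)
  expect_identical(nrow(sm2$moves), 0L)
})

test_that("moves require the same TF and the same locus", {
  old <- ann_df("Bcd", "hb", 100, 10)
  other_tf <- ann_df("Kr", "hb", 105, 9)
  sm <- step_match(old, other_tf)
  expect_length(sm$deaths, 1)
  expect_length(sm$births, 1)
  other_locus <- ann_df("Bcd", "Kr", 105, 10)
  sm2 <- step_match(old, other_locus)
  expect_length(sm2$deaths, 1)
  expect_length(sm2$births, 1)
})

test_that("greedy matching takes the nearest candidate with low-coordinate tie-break", {
  old <- ann_df(c("Bcd", "Bcd"), "hb", c(100, 120), 10)
  new <- ann_df("Bcd", "hb", 112, 10)
  sm <- step_match(old, new)
  ## 112 is 12 from 100 and 8 from 120: the site at 120 wins the match
  expect_identical(unname(sm$moves[, "old"]), 2L)
  expect_length(sm$deaths, 1)
  ## exact tie in distance: the smaller old coordinate wins
  old2 <- ann_df(c("Bcd", "Bcd"), "hb", c(100, 124), 10)
  new2 <- ann_df("Bcd", "hb", 112, 10)
  sm2 <- step_match(old2, new2)
  expect_identical(unname(sm2$moves[, "old"]), 1L)
})

test_that("event bookkeeping conserves counts on random annotation pairs", {
  set.seed(55)
  for (rep in 1:40) {
    a <- random_annotation(sample(0:12, 1))
    b <- random_annotation(sample(0:12, 1))
    sm <- step_match(a, b)
    expect_identical(nrow(sm$persist) + nrow(sm$moves) +
                       length(sm$deaths), nrow(a))
    expect_identical(nrow(sm$persist) + nrow(sm$moves) +
                       length(sm$births), nrow(b))
  }
})

test_that("step_match agrees with the exhaustive assignment oracle on small cases", {
  ## oracle: recursively enumerate every one-to-one matching between the
  ## non-exact old and new sites that satisfies the same-TF
  ## vicinity-overlap rule; the optimum maximises the number of matched
  ## pairs and, among those, minimises total displacement
  brute <- function(a, b) {
    am <- regevo:::ann_df_to_matrix(a); bm <- regevo:::ann_df_to_matrix(b)
    okey <- regevo:::site_keys(am); nkey <- regevo:::site_keys(bm)
    exact_o <- which(okey %in% nkey)
    exact_n <- match(okey[exact_o], nkey)
    of <- setdiff(seq_len(nrow(am)), exact_o)
    nf <- setdiff(seq_len(nrow(bm)), exact_n)
    ok <- function(oi, ni)
      am[oi, "tf"] == bm[ni, "tf"] && am[oi, "locus"] == bm[ni, "locus"] &&
      (bm[ni, "start"] + bm[ni, "len"]) > (am[oi, "start"] - am[oi, "len"]) &&
      bm[ni, "start"] < (am[oi, "start"] + 2 * am[oi, "len"])
    best <- list(npair = -1L, disp = Inf)
    rec <- function(i, used, pairs, disp) {
      if (i > length(of)) {
        np <- nrow(pairs)
        if (np > best$npair || (np == best$npair && disp < best$disp))
          best <<- list(npair = np, disp = disp, pairs = pairs)
        return(invisible())
      }
      rec(i + 1L, used, pairs, disp)          # old site unmatched
      for (j in seq_along(nf)) {
        if (used[j] || !ok(of[i], nf[j])) next
        used[j] <- TRUE
        rec(i + 1L, used,
            rbind(pairs, c(of[i], nf[j])),
            disp + abs(am[of[i], "start"] - bm[nf[j], "start"]))
        used[j] <- FALSE
      }
    }
    rec(1L, logical(length(nf)),
        matrix(integer(0), 0, 2), 0)
    list(npair = best$npair, disp = best$disp)
  }
  ## exact agreement with the oracle on the constructed suite cases
  cases <- list(
    list(ann_df(c("Bcd", "Bcd"), "hb", c(100, 120), 10),
         ann_df("Bcd", "hb", 112, 10)),
    list(ann_df(c("Bcd", "Bcd"), "hb", c(100, 124), 10),
         ann_df("Bcd", "hb", 112, 10)),
    list(ann_df("Bcd", "hb", 100, 10),
         ann_df("Bcd", "hb", 150, 10)),
    list(ann_df(c("Bcd", "Kr"), "hb", c(100, 130), c(8, 9)),
         ann_df(c("Bcd", "Kr"), "hb", c(108, 122), c(8, 9))),
    list(ann_df(c("Hb", "Hb", "Hb"), "hb", c(50, 60, 70), 8),
         ann_df(c("Hb", "Hb"), "hb", c(55, 73), 8)),
    list(ann_df("Gt", "hb", 10, 10),
         ann_df(c("Gt", "Gt"), "hb", c(5, 25), 10)))
  for (cs in cases) {
    sm <- step_match(cs[[1]], cs[[2]])
    want <- brute(cs[[1]], cs[[2]])
    n_exact <- sum(regevo:::site_keys(regevo:::ann_df_to_matrix(cs[[1]]))
                   %in%
                   regevo:::site_keys(regevo:::ann_df_to_matrix(cs[[2]])))
    expect_identical(nrow(sm$persist), n_exact)
    expect_identical(nrow(sm$moves), want$npair)
    expect_identical(nrow(sm$persist) + nrow(sm$moves) + length(sm$deaths),
                     nrow(cs[[1]]))
  }
  ## on random cases the greedy matching must at least be maximal:
  ## no remaining old/new pair still satisfies the matching rule
  set.seed(66)
  for (rep in 1:20) {
    a <- random_annotation(sample(2:7, 1), loci_lengths = c(hb = 120),
                           tfs = c("Bcd", "Hb"))
    b <- random_annotation(sample(2:7, 1), loci_lengths = c(hb = 120),
                           tfs = c("Bcd", "Hb"))
    sm <- step_match(a, b)
    am <- regevo:::ann_df_to_matrix(a); bm <- regevo:::ann_df_to_matrix(b)
    for (oi in sm$deaths) for (ni in sm$births) {
      matchable <- am[oi, "tf"] == bm[ni, "tf"] &&
        (bm[ni, "start"] + bm[ni, "len"]) >
          (am[oi, "start"] - am[oi, "len"]) &&
        bm[ni, "start"] < (am[oi, "start"] + 2 * am[oi, "len"])
      expect_false(matchable)
    }
  }
})

test_that("a three-generation history classifies persist, move, death, birth and rebirth", {
  ## g0: two Bcd sites and one Kr site
  g0 <- ann_df(c("Bcd", "Bcd", "Kr"), "hb", c(100, 300, 500),
               c(8, 8, 9))
  ## g1: site A persists, site B (300) dies, Kr site moves to 505
  g1 <- ann_df(c("Bcd", "Kr"), "hb", c(100, 505), c(8, 9))
  ## g2: a Bcd site appears at 310 - inside the vicinity [292, 316) of
  ## the dead wild-type site B -> rebirth; another Bcd site appears at
  ## 700 -> plain birth
  g2 <- ann_df(c("Bcd", "Kr", "Bcd", "Bcd"), "hb",
               c(100, 505, 310, 700), c(8, 9, 8, 8))
  run <- fake_run(list(g0, g1, g2))
  tracks <- track_sites(run)
  tr <- tracks$trajectories
  expect_identical(nrow(tr), 5L)
  expect_identical(tr$origin, c("initial", "initial", "initial",
                                "rebirth", "born"))
  expect_identical(tr$death_gen, c(NA_integer_, 1L, NA_integer_,
                                   NA_integer_, NA_integer_))
  expect_identical(tr$rebirth_of, c(NA_integer_, NA_integer_,
                                    NA_integer_, 2L, NA_integer_))
  expect_identical(tr$moves, c(0L, 0L, 1L, 0L, 0L))
  ## lifetimes: B lived 1 generation; the others are censored at G = 2
  lt <- lifetimes(tracks)
  expect_identical(lt$lifetime, c(2L, 1L, 2L, 0L, 0L))
  expect_identical(lt$censored, c(TRUE, FALSE, TRUE, TRUE, TRUE))
})

test_that("a birth in the vicinity of a still-alive wild-type site is a plain birth", {
  g0 <- ann_df("Bcd", "hb", 100, 8)
  g1 <- ann_df(c("Bcd", "Bcd"), "hb", c(100, 110), 8)
  run <- fake_run(list(g0, g1))
  tr <- track_sites(run)$trajectories
  expect_identical(tr$origin, c("initial", "born"))
  expect_true(all(is.na(tr$rebirth_of)))
})

test_that("a birth with no same-TF wild-type site on the locus is a plain birth", {
  g0 <- ann_df("Kr", "hb", 100, 9)
  g1 <- ann_df(c("Kr", "Bcd"), "hb", c(100, 102), c(9, 8))
  run <- fake_run(list(g0, g1))
  tr <- track_sites(run)$trajectories
  expect_identical(tr$origin[2], "born")
  expect_true(is.na(tr$rebirth_of[2]))
})

test_that("core sites are initial trajectories alive at every generation", {
  g0 <- ann_df(c("Bcd", "Hb", "Kr"), "hb", c(100, 300, 500), c(8, 8, 9))
  g1 <- ann_df(c("Bcd", "Kr"), "hb", c(104, 500), c(8, 9))  # Hb dies, Bcd moves
  g2 <- ann_df(c("Bcd", "Kr", "Hb"), "hb", c(104, 500, 302), c(8, 9, 8))
  run <- fake_run(list(g0, g1, g2))
  tracks <- track_sites(run)
  core <- core_sites(tracks)
  ## Bcd (moved, still alive) and Kr (identical throughout) are core;
  ## the dead-then-reborn Hb initial trajectory is not
  expect_setequal(core$id, c(1L, 3L))
  expect_identical(core$identical_coords[core$id == 3], TRUE)
  expect_identical(core$identical_coords[core$id == 1], FALSE)
})

test_that("neighbour classification: cooperative beats overlapping, distances respected", {
  ## core site: Bcd at 100 (alive throughout); neighbours classified by
  ## origin coordinates
  g0 <- ann_df(c("Bcd", "Bcd", "Kr", "Bcd", "Hb"), "hb",
               c(100, 130, 96, 400, 104), c(8, 8, 9, 8, 8))
  ## all but the core Bcd die at g1
  g1 <- ann_df("Bcd", "hb", 100, 8)
  run <- fake_run(list(g0, g1))
  tracks <- track_sites(run)
  core <- core_sites(tracks)
  expect_identical(core$id, 1L)
  nb <- classify_neighbors(tracks, coop_range = 50)
  cls <- setNames(nb$class, nb$id)
  ## Bcd at 130: same TF, 22 bp edge gap -> cooperative
  expect_identical(unname(cls["2"]), "cooperative")
  ## Kr at 96: different TF, interval overlaps the core -> overlapping
  expect_identical(unname(cls["3"]), "overlapping")
  ## Bcd at 400: same TF but 292 bp away -> other
  expect_identical(unname(cls["4"]), "other")
  ## Hb at 104: different TF, overlaps core -> overlapping
  expect_identical(unname(cls["5"]), "overlapping")
  ## same-TF site overlapping the core is cooperative (precedence)
  g0b <- ann_df(c("Bcd", "Bcd"), "hb", c(100, 104), 8)
  g1b <- ann_df("Bcd", "hb", 100, 8)
  run2 <- fake_run(list(g0b, g1b))
  nb2 <- classify_neighbors(track_sites(run2))
  expect_identical(nb2$class, "cooperative")
})

test_that("lifetimes of a constructed multi-event history match hand enumeration", {
  ## trajectory lives g0..g3, dies at g4; a born site at g2 dies at g3
  g0 <- ann_df("Gt", "hb", 50, 10)
  g1 <- g0; g2 <- ann_df(c("Gt", "Cad"), "hb", c(50, 200), c(10, 8))
  g3 <- ann_df("Gt", "hb", 50, 10)
  g4 <- ann_df("Cad", "hb", 400, 8)
  run <- fake_run(list(g0, g1, g2, g3, g4))
  tracks <- track_sites(run)
  lt <- lifetimes(tracks)
  tr <- tracks$trajectories
  expect_identical(lt$lifetime[tr$origin == "initial"], 4L)
  expect_identical(lt$censored[tr$origin == "initial"], FALSE)
  born <- tr$origin %in% c("born")
  ## Cad born at g2 died at g3 (lifetime 1); Cad born at g4 censored
  expect_setequal(lt$lifetime[born], c(1L, 0L))
})
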