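test_that("the >0.5 s rule converts events to 1 s tracks", {
  tr <- to_track(event_list(10, 3), 20)
  expect_equal(which(tr) - 1, c(10, 11, 12))

  # 1 s event at 10.6: 0.4 s in epoch 10 (no), 0.6 s in epoch 11 (yes)
  tr2 <- to_track(event_list(10.6, 1), 20)
  expect_equal(which(tr2) - 1, 11)

  # exactly 0.5 s in each epoch: strictly-more-than rule labels neither
  tr3 <- to_track(event_list(10.5, 1), 20)
  expect_equal(sum(tr3), 0)

  expect_error(to_track(event_list(18, 5), 20), "past the end")
})

test_that("inclusive fusion is the union; conservative keeps only co-detected events", {
  a <- to_track(event_list(c(10, 40), c(5, 4)), 60)
  b <- to_track(event_list(c(13, 50), c(5, 4)), 60)

  inc <- fuse_raters(a, b, "inclusive")
  expect_equal(which(inc) - 1, sort(unique(c(10:14, 40:43, 13:17, 50:53))))
  expect_true(all(inc[a] & inc[b]))

  # a 10-15 vs b 13-18: overlap 2 s -> conservative union interval 10-18
  con <- fuse_raters(a, b, "conservative")
  expect_equal(which(con) - 1, 10:17)
  con_i <- fuse_raters(a, b, "conservative", granularity = "intersection")
  expect_equal(which(con_i) - 1, 13:14)

  # disjoint events: inclusive has both, conservative none
  d1 <- to_track(event_list(5, 3), 30)
  d2 <- to_track(event_list(20, 3), 30)
  expect_equal(sum(fuse_raters(d1, d2, "inclusive")), 6)
  expect_equal(sum(fuse_raters(d1, d2, "conservative")), 0)

  # identical tracks: both modes are the identity
  expect_equal(as.logical(fuse_raters(a, a, "inclusive")), as.logical(a))
  expect_equal(as.logical(fuse_raters(a, a, "conservative")), as.logical(a))
})

test_that("confusion matches the brute-force oracle on random tracks", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(c(50, 200), 1)
    test <- as_track(runif(n) < runif(1, 0.05, 0.5))
    gold <- as_track(runif(n) < runif(1, 0.05, 0.5))
    got <- confusion(test, gold)
    want <- oracle_confusion(as.logical(test), as.logical(gold))
    for (f in c("TPs", "FPs", "TNs", "FNs", "TPe", "FPe", "FNe"))
      expect_identical(as.integer(got[[f]]), as.integer(want[[f]]))
  }
})

test_that("identical and fully shifted tracks give the textbook counts", {
  g <- to_track(event_list(c(5, 20, 40), c(3, 4, 5)), 60)
  cc <- confusion(g, g)
  expect_equal(cc$TPe, 3); expect_equal(cc$FPe, 0); expect_equal(cc$FNe, 0)
  expect_equal(cc$FPs, 0); expect_equal(cc$FNs, 0)

  t2 <- to_track(event_list(c(8, 24, 45), c(3, 4, 5)), 60)  # shifted past
  cc2 <- confusion(t2, g)
  expect_equal(cc2$TPe, 0); expect_equal(cc2$FPe, 3); expect_equal(cc2$FNe, 3)
})

test_that("the five coefficients follow their definitions", {
  g <- to_track(event_list(c(5, 20), c(4, 4)), 50)
  perfect <- coefficients(confusion(g, g))
  expect_equal(perfect$S, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(coefficients(confusion(g, g), "paper-literal")$kappa <= 1, TRUE)
  expect_equal(perfect$Se, 1)
  expect_equal(perfect$C, 1)
  expect_equal(perfect$FDR, 0)

  compl <- coefficients(confusion(as_track(!as.logical(g)), g))
  expect_equal(compl$P0, 0)
  expect_equal(compl$S, -1)

  # hand-worked contingency: TPs=50, FPs=50, FNs=50, TNs=850 (n=1000)
  counts <- structure(list(TPs = 50, FPs = 50, TNs = 850, FNs = 50,
                           TPe = 1, FPe = 0, FNe = 0, n = 1000,
                           matched = data.frame(gold_len = 10, overlap = 5)),
                      class = "confusion_counts")
  co <- coefficients(counts)
  expect_equal(co$P0, 0.9)
  expect_equal(co$S, 0.8)
  # Pe = (100*100 + 900*900)/1e6 = 0.82 -> kappa = (0.9-0.82)/0.18 = 4/9
  expect_equal(co$kappa, 4 / 9)
  expect_equal(co$C, 0.5)
  # printed-variant chance term: Pr = (900*100)/1e6 = 0.09
  co2 <- coefficients(counts, "paper-literal")
  expect_equal(co2$kappa, (0.9 - 0.09) / (1 - 0.09))
  expect_equal(co2$kappa_variant, "paper-literal")

  # undefined ratios surface as NA with a reason, never silently
  empty <- coefficients(confusion(as_track(rep(FALSE, 20)),
                                  as_track(rep(FALSE, 20))))
  expect_true(is.na(empty$Se))
  expect_true(is.na(empty$FDR))
  expect_true(any(grepl("undefined", empty$notes)))
})

test_that("standard kappa never exceeds the observed accuracy", {
  set.seed(18)
  for (i in 1:100) {
    test <- as_track(runif(100) < 0.3)
    gold <- as_track(runif(100) < 0.3)
    co <- coefficients(confusion(test, gold))
    if (!is.na(co$kappa)) expect_lte(co$kappa, co$P0 + 1e-12)
  }
})

test_that("fusion bounds: inclusive covers both raters, conservative no more than either", {
  set.seed(19)
  for (i in 1:50) {
    a <- as_track(runif(120) < 0.25)
    b <- as_track(runif(120) < 0.25)
    inc <- fuse_raters(a, b, "inclusive")
    expect_true(all(as.logical(inc) >= as.logical(a)))
    expect_true(all(as.logical(inc) >= as.logical(b)))
    con <- fuse_raters(a, b, "conservative")
    n_ev <- function(tr) length(oracle_events(as.logical(tr)))
    expect_lte(n_ev(con), min(n_ev(a), n_ev(b)))
  }
})

test_that("kappa values map to the agreement scale bands", {
  expect_equal(kappa_interpretation(0.95), "Almost perfect")
  expect_equal(kappa_interpretation(-0.1), "Poor")
  expect_equal(kappa_interpretation(0.50), "Moderate")
  expect_equal(kappa_interpretation(0.20), "Slight")
  expect_equal(kappa_interpretation(0.21), "Fair")
  expect_equal(kappa_interpretation(0.61), "Substantial")
  expect_equal(kappa_interpretation(0.80), "Substantial")
  expect_equal(kappa_interpretation(1), "Almost perfect")
  expect_error(kappa_interpretation(1.2))
})

test_that("per-stage stratified agreement restricts the epoch comparison", {
  hyp <- hypnogram(c("N2", "REM"))
  test <- as_track(c(rep(TRUE, 10), rep(FALSE, 20), rep(FALSE, 30)))
  gold <- as_track(c(rep(TRUE, 10), rep(FALSE, 20), rep(TRUE, 5),
                     rep(FALSE, 25)))
  st <- stage_agreement(test, gold, hyp)
  expect_equal(sort(st$stage), c("N2", "REM"))
  expect_equal(st$S[st$stage == "N2"], 1)          # perfect in N2
  expect_equal(st$S[st$stage == "REM"], 2 * (25 / 30) - 1)
})
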