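# spectral generator for discriminant tests: one planted carbon bin that
# potent compounds hit with high probability
make_planted_spectra <- function(n, p_potent_hit = 0.9, p_weak_hit = 0.05,
                                 seed = 1, n_background = 8) {
  set.seed(seed)
  labels <- rep(c("P", "W"), length.out = n)
  ids <- sprintf("c%03d", seq_len(n))
  rows <- lapply(seq_len(n), function(k) {
    shifts <- runif(n_background, 0, 200)
    hit <- runif(1) < (if (labels[k] == "P") p_potent_hit else p_weak_hit)
    if (hit) shifts <- c(shifts, 176.5)
    data.frame(id = ids[k], nucleus = "13C", shift = shifts)
  })
  list(peaks = do.call(rbind, rows), ids = ids, labels = labels)
}

test_that("peaks land in floor-indexed, nucleus-namespaced bins", {
  peaks <- data.frame(id = c("a", "a", "b", "b"),
                      nucleus = c("13C", "15N", "13C", "13C"),
                      shift = c(127.4, 212.3, 10.1, 10.9))
  m <- bin_spectra(peaks)
  expect_equal(m["a", "C127"], 1L)
  expect_equal(m["a", "N42"], 1L)
  expect_equal(m["b", "C10"], 2L)

  mb <- bin_spectra(peaks, binary = TRUE)
  expect_equal(mb["b", "C10"], 1L)

  # translation by one bin width shifts every carbon index by one
  peaks_c <- peaks[peaks$nucleus == "13C", ]
  m1 <- bin_spectra(peaks_c)
  peaks_shift <- transform(peaks_c, shift = shift + 1)
  m2 <- bin_spectra(peaks_shift)
  idx <- function(m) sort(as.integer(sub("C", "", colnames(m))))
  expect_equal(idx(m2), idx(m1) + 1L)

  expect_warning(bin_spectra(peaks, ids = c("a", "b", "ghost")), "ghost")
})

test_that("bin population filter requires three distinct compounds", {
  m <- matrix(c(2, 1, 0, 0,
                1, 1, 1, 0,
                5, 0, 0, 0), nrow = 4,
              dimnames = list(sprintf("c%d", 1:4), c("C1", "C2", "C3")))
  f <- filter_bins(m)
  expect_equal(colnames(f), "C2")  # hit by 3 compounds
  expect_equal(sort(colnames(filter_bins(m, min_compounds = 2))),
               c("C1", "C2"))
  empty <- m[, 0]
  expect_equal(ncol(filter_bins(empty)), 0)
})

test_that("forward selection enters the planted bin first", {
  hits <- 0
  for (s in 1:10) {
    d <- make_planted_spectra(120, seed = s)
    m <- filter_bins(bin_spectra(d$peaks, ids = d$ids))
    fit <- train_discriminant(m, d$labels, max_bins = 1)
    if (length(fit$bins) && fit$bins[1] == "C176") hits <- hits + 1
  }
  expect_equal(hits, 10)
})

test_that("the planted bin's entry F dominates the permutation null", {
  d <- make_planted_spectra(120, seed = 3)
  m <- filter_bins(bin_spectra(d$peaks, ids = d$ids))
  fit <- train_discriminant(m, d$labels, max_bins = 1)
  f_signal <- fit$f_values[[1]]
  # permutation null of the best entry F: scanning many candidate bins
  # makes single false entries at F > 4 common, but the planted signal
  # must exceed every permuted maximum (permutation p < 1/21)
  set.seed(99)
  f_null <- replicate(20, {
    train_discriminant(m, sample(d$labels), max_bins = 1)$f_values[[1]]
  })
  expect_equal(fit$bins[1], "C176")
  expect_gt(f_signal, max(f_null))
  expect_gt(f_signal, 4)
})

test_that("duplicate bins are not co-selected", {
  d <- make_planted_spectra(80, seed = 5)
  m <- filter_bins(bin_spectra(d$peaks, ids = d$ids))
  m_dup <- cbind(m, C999 = m[, "C176"])
  fit <- train_discriminant(m_dup, d$labels)
  expect_lte(sum(fit$bins %in% c("C176", "C999")), 1)
})

test_that("selection respects the filter and the size cap", {
  d <- make_planted_spectra(60, seed = 6)
  m_all <- bin_spectra(d$peaks, ids = d$ids)
  m <- filter_bins(m_all)
  fit <- train_discriminant(m, d$labels)
  expect_true(all(fit$bins %in% colnames(m)))
  expect_lte(length(fit$bins), nrow(m) - 2)
  expect_true(all(fit$f_values > 4))
})

test_that("classification recovers centroids and symmetric posteriors", {
  # two informative bins; counts vary within class so the pooled
  # within-class covariance stays regular
  p_counts <- rep(c(3L, 4L), 5)
  m <- rbind(cbind(C10 = p_counts, C20 = 0L),
             cbind(C10 = 0L, C20 = p_counts))
  rownames(m) <- sprintf("c%02d", 1:20)
  labels <- rep(c("P", "W"), each = 10)
  fit <- train_discriminant(m, labels)
  cl <- classify_sdar(fit, m)
  expect_equal(cl$call, labels)
  expect_true(all(cl$posterior_p[1:10] > 0.5))

  # a row equidistant from both centroids scores one half
  mid <- matrix(1.75, 1, 2, dimnames = list("mid", c("C10", "C20")))
  expect_equal(classify_sdar(fit, mid)$posterior_p, 0.5, tolerance = 1e-9)

  # a row with none of the selected bins is flagged low-information
  none <- matrix(0L, 1, 2, dimnames = list("void", c("C10", "C20")))
  expect_true(classify_sdar(fit, none)$low_information)

  # a bin that is constant within both classes is skipped with a warning
  m_sing <- cbind(m, C99 = rep(c(5L, 0L), each = 10))
  expect_warning(train_discriminant(m_sing, labels), "singular")
})

test_that("held-out accuracy beats 0.8 with informative carbon and nitrogen bins", {
  accs <- numeric(10)
  for (s in 1:10) {
    cfg <- synth_config()
    train <- gen_compounds(240, cfg, seed = 1000 + s)
    test <- gen_compounds(120, cfg, seed = 2000 + s)
    m_tr <- filter_bins(bin_spectra(gen_spectra(train, cfg, seed = 3000 + s),
                                    ids = train$id))
    fit <- train_discriminant(m_tr, train$category)
    m_te <- bin_spectra(gen_spectra(test, cfg, seed = 4000 + s),
                        ids = test$id)
    accs[s] <- mean(classify_sdar(fit, m_te)$call == test$category)
  }
  expect_gt(mean(accs), 0.8)
})
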