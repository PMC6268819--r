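# helpers used across the docking-classifier tests
make_informative_scores <- function(n, n_cols = 10, effect = 1.2,
                                    seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * n_cols), nrow = n,
              dimnames = list(NULL, sprintf("s%02d", seq_len(n_cols))))
  labels <- rep(c("P", "W"), length.out = n)
  m[labels == "P", 1] <- m[labels == "P", 1] + effect
  list(z = standardize_scores(m), labels = labels)
}

test_that("standardization stores and reuses training statistics", {
  m <- matrix(c(1, 2, 3, 10, 20, 30), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  z <- standardize_scores(m)
  expect_equal(z[, "a"], c(-1, 0, 1))
  zp <- standardize_scores(m, sd_type = "population")
  expect_equal(zp[, "a"], c(-1, 0, 1) * sqrt(3 / 2))

  st <- attr(z, "standardization")
  z_new <- standardize_scores(matrix(c(2, 20), 1, 2,
                                     dimnames = list(NULL, c("a", "b"))),
                              stats = st)
  expect_equal(as.vector(z_new), c(0, 0))  # training means map to zero

  m_const <- cbind(m, cst = c(5, 5, 5))
  expect_error(standardize_scores(m_const), "cst")

  # re-standardizing the training matrix is idempotent in its statistics
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-9)
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1), tolerance = 1e-9)
})

test_that("logistic fit matches a direct likelihood-maximization oracle", {
  set.seed(21)
  n <- 40
  x <- matrix(rnorm(n * 2), ncol = 2, dimnames = list(NULL, c("u", "v")))
  eta <- -0.5 + 1.2 * x[, 1] - 0.8 * x[, 2]
  y <- rbinom(n, 1, plogis(eta))
  labels <- ifelse(y == 1, "P", "W")

  fit <- fit_logistic(x, labels)

  # independent oracle: numeric maximization of the Bernoulli log-likelihood
  nll <- function(b) {
    e <- b[1] + x %*% b[2:3]
    -sum(y * e - log1p(exp(e)))
  }
  oracle <- optim(c(0, 0, 0), nll, method = "BFGS",
                  control = list(reltol = 1e-14))$par
  expect_equal(unname(c(fit$intercept, fit$coefficients)), oracle,
               tolerance = 1e-4)
})

test_that("Wald statistics follow the (coef/SE)^2 identity", {
  m <- dlr_published_model()
  tab <- m$table
  expect_equal(tab$wald_chisq, (tab$coefficient / tab$se)^2)
  intercept_chisq <- tab$wald_chisq[tab$term == "(Intercept)"]
  expect_equal(intercept_chisq, 25.88, tolerance = 0.01 / 25.88)
})

test_that("a symmetric balanced problem yields a null intercept", {
  x <- matrix(c(1, -1, 2, -2, 1, -1), ncol = 1,
              dimnames = list(NULL, "s"))
  labels <- c("P", "W", "P", "W", "W", "P")
  fit <- fit_logistic(x, labels)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
})

test_that("coefficients are recovered within 3 SE at large n", {
  set.seed(31)
  n <- 2000
  beta <- c(-0.7, 1.1, -0.6, 0.4)
  x <- matrix(rnorm(n * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(beta[1] + x %*% beta[-1]))
  fit <- fit_logistic(x, ifelse(y == 1, "P", "W"))
  est <- c(fit$intercept, fit$coefficients)
  se <- fit$table$se[match(c("(Intercept)", "a", "b", "c"),
                           fit$table$term)]
  expect_true(all(abs(est - beta) < 3 * se))
})

test_that("forward selection finds the informative column first", {
  hits <- 0
  for (s in 1:10) {
    d <- make_informative_scores(500, seed = s)
    fit <- select_stepwise(d$z, d$labels, "forward")
    if (length(fit$coefficients) &&
        names(fit$coefficients)[1] == "s01") hits <- hits + 1
  }
  expect_equal(hits, 10)
})

test_that("forward selection on pure noise admits few columns", {
  set.seed(52)
  n_selected <- integer(20)
  for (s in 1:20) {
    m <- matrix(rnorm(200 * 10), ncol = 10,
                dimnames = list(NULL, sprintf("s%02d", 1:10)))
    labels <- rep(c("P", "W"), each = 100)
    fit <- select_stepwise(m, labels, "forward")
    n_selected[s] <- length(fit$coefficients)
  }
  # per-column type-I control at alpha = 0.05: with 10 candidates the
  # family-wise false-entry chance per step is moderate, but runs admitting
  # several noise columns must stay rare
  expect_lt(mean(n_selected), 1.5)
  expect_gte(mean(n_selected == 0), 0.4)
})

test_that("backward selection retains the informative column", {
  for (s in 1:5) {
    d <- make_informative_scores(500, seed = s + 100)
    fit <- select_stepwise(d$z, d$labels, "backward")
    expect_true("s01" %in% names(fit$coefficients))
  }
})

test_that("manual selection keeps significant terms and honors the AUC floor", {
  d <- make_informative_scores(400, n_cols = 8, effect = 1.5, seed = 7)
  full <- fit_logistic(d$z, d$labels)
  p <- setNames(full$table$p_value, full$table$term)
  significant <- setdiff(names(p)[p <= 0.05], "(Intercept)")
  man <- select_manual(d$z, d$labels)
  expect_true(all(significant %in% names(man$coefficients)))
  extras <- setdiff(names(man$coefficients), significant)
  expect_true(all(p[extras] < 0.10))
  expect_true(man$auc_floor_reached)
  expect_gt(man$training_auc, 0.8)

  # every column significant -> identical to the full model
  d2 <- list(z = d$z[, 1, drop = FALSE], labels = d$labels)
  man2 <- select_manual(d2$z, d2$labels)
  full2 <- fit_logistic(d2$z, d2$labels)
  expect_equal(man2$coefficients, full2$coefficients)

  # nothing significant and the floor unreachable -> flagged fallback with
  # the single best column
  set.seed(77)
  m_noise <- matrix(rnorm(120 * 6), ncol = 6,
                    dimnames = list(NULL, sprintf("n%d", 1:6)))
  labs <- rep(c("P", "W"), each = 60)
  man3 <- select_manual(m_noise, labs)
  expect_false(man3$auc_floor_reached)
  expect_lte(length(man3$coefficients), 6)
  expect_gte(length(man3$coefficients), 1)
})

test_that("ROC analysis matches the rank statistic and names its points", {
  # perfectly separated probabilities
  labels <- rep(c("P", "W"), each = 20)
  probs <- c(runif(20, 0.8, 1), runif(20, 0, 0.2))
  rc <- roc_curve(NULL, NULL, labels, probabilities = probs)
  expect_equal(rc$auc, 1.0)

  # AUC equals the Mann-Whitney statistic of the scores exactly
  set.seed(41)
  for (s in 1:5) {
    probs <- round(runif(60), 2)  # coarse grid forces ties
    labels <- sample(rep(c("P", "W"), c(25, 35)))
    rc <- roc_curve(NULL, NULL, labels, probabilities = probs)
    rk <- rank(probs)
    n1 <- sum(labels == "P")
    n2 <- sum(labels == "W")
    u <- sum(rk[labels == "P"]) - n1 * (n1 + 1) / 2
    expect_equal(rc$auc, u / (n1 * n2), tolerance = 1e-12)
  }

  # large balanced noise -> AUC near one half
  set.seed(43)
  probs <- runif(2000)
  labels <- rep(c("P", "W"), 1000)
  expect_equal(roc_curve(NULL, NULL, labels, probabilities = probs)$auc,
               0.5, tolerance = 0.05)

  # named operating points are ordered as cutoffs
  d <- make_informative_scores(200, seed = 9)
  fit <- fit_logistic(d$z, d$labels, "s01")
  rc <- roc_curve(fit, d$z, d$labels)
  pts <- rc$points
  expect_equal(pts$point, c("A", "B", "C", "D"))
  expect_gte(pts$cutoff[pts$point == "A"], pts$cutoff[pts$point == "D"])
  expect_equal(pts$specificity[pts$point == "A"],
               max(rc$grid$specificity[rc$grid$sensitivity > 0]))
  expect_equal(pts$accuracy[pts$point == "B"], max(rc$grid$accuracy))
})

test_that("independent ROC implementation agrees on the AUC", {
  set.seed(45)
  probs <- runif(150)
  labels <- sample(rep(c("P", "W"), c(60, 90)))
  rc <- roc_curve(NULL, NULL, labels, probabilities = probs)
  ref <- pROC::auc(pROC::roc(response = labels, predictor = probs,
                             levels = c("W", "P"), direction = "<",
                             quiet = TRUE))
  expect_equal(rc$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("fixed published coefficients score compounds deterministically", {
  model <- dlr_published_model()
  z0 <- setNames(rep(0, 7), names(model$coefficients))
  sc <- score_probability(model, z0)
  expect_equal(sc$probability, plogis(-1.8088), tolerance = 1e-12)
  expect_equal(round(sc$probability, 3), 0.141)
  expect_equal(sc$call, "W")

  z1 <- z0
  z1["surflex.1W0F.catalytic"] <- 1
  sc1 <- score_probability(model, z1)
  expect_equal(sc1$probability, plogis(5.5653 - 1.8088), tolerance = 1e-12)
  expect_equal(sc1$call, "P")

  set.seed(10)
  z_many <- matrix(rnorm(50 * 7), ncol = 7,
                   dimnames = list(NULL, names(model$coefficients)))
  p <- score_probability(model, z_many)$probability
  expect_true(all(p > 0 & p < 1))

  expect_error(score_probability(model, z0[-1]), "missing model column")
})

test_that("the truncated applicability domain keeps the high-MW band", {
  tr <- cyp3a4_training()
  dom <- truncate_domain(tr)
  expect_equal(length(dom$inside), 39)
  cat_in <- tr$category[match(dom$inside, tr$id)]
  expect_equal(sum(cat_in == "P"), 18)
  expect_equal(sum(cat_in == "W"), 21)
  expect_true("propofol" %in% dom$outside)

  low_only <- tr[tr$band == "LOW", ]
  expect_error(truncate_domain(low_only), "empty applicability domain")
})
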