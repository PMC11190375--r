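test_that("instance embedding matches a straight-line oracle", {
  # all-zero weights: output all zeros
  pz <- list(W1 = matrix(0, 3, 4), b1 = rep(0, 3),
             W2 = matrix(0, 2, 3), b2 = rep(0, 2))
  X <- matrix(rnorm(12), 3, 4)
  expect_true(all(embed_instances(X, pz) == 0))

  # identity blocks on nonnegative input: rectifier is the identity
  pi4 <- list(W1 = diag(4), b1 = rep(0, 4), W2 = diag(4), b2 = rep(0, 4))
  Xp <- matrix(abs(rnorm(8)), 2, 4)
  expect_equal(embed_instances(Xp, pi4), Xp)

  # seeded parameters on a fixed 3x4 input vs direct recomputation
  set.seed(77)
  p <- list(W1 = matrix(rnorm(20), 5, 4), b1 = rnorm(5),
            W2 = matrix(rnorm(10), 2, 5), b2 = rnorm(2))
  H <- embed_instances(X, p)
  for (k in 1:3) {
    z1 <- pmax(p$W1 %*% X[k, ] + p$b1, 0)
    hk <- pmax(p$W2 %*% z1 + p$b2, 0)
    expect_equal(H[k, ], drop(hk), tolerance = 1e-6)
  }

  expect_error(embed_instances(matrix(1, 2, 3), p), "dimension")
})

test_that("gated attention pooling obeys softmax and convexity rules", {
  set.seed(5)
  ap <- attention_params(attn_dim = 3, embed_dim = 4, n_heads = 2, seed = 2)

  # K = 1: weight 1, pooled equals the single row
  h1 <- matrix(rnorm(4), 1, 4)
  out1 <- gated_attention_pool(h1, ap)
  expect_equal(unname(out1$weights[, 1]), 1)
  expect_equal(out1$pooled[[1]], drop(h1))

  # identical rows: uniform weights, pooled equals the common row
  hr <- matrix(rep(rnorm(4), each = 5), 5, 4)
  outr <- gated_attention_pool(hr, ap)
  expect_equal(unname(outr$weights[, 1]), rep(0.2, 5))
  expect_equal(outr$pooled[[2]], hr[1, ])

  # weights nonnegative, sum to one; z within coordinate-wise min/max
  H <- matrix(rnorm(24), 6, 4)
  out <- gated_attention_pool(H, ap)
  expect_true(all(out$weights >= 0))
  expect_equal(colSums(out$weights), rep(1, 2), tolerance = 1e-8)
  for (j in 1:2) {
    expect_true(all(out$pooled[[j]] >= apply(H, 2, min) - 1e-12))
    expect_true(all(out$pooled[[j]] <= apply(H, 2, max) + 1e-12))
  }

  expect_error(gated_attention_pool(H[0, , drop = FALSE], ap), "instance")
})

test_that("gated attention matches the printed-equation oracle on a fixed fixture", {
  # L = M = 2, K = 3 with explicitly listed values
  H <- matrix(c(0.5, -0.2,
                1.0, 0.3,
                -0.4, 0.8), 3, 2, byrow = TRUE)
  w <- c(0.7, -1.1)
  U <- matrix(c(0.2, -0.5, 0.9, 0.1), 2, 2, byrow = TRUE)
  V <- matrix(c(-0.3, 0.6, 0.4, -0.8), 2, 2, byrow = TRUE)
  out <- gated_attention_pool(H, list(w = w, U = U, V = V))
  oracle <- brute_gated_attention(H, w, U, V)
  expect_equal(unname(out$weights[, 1]), oracle$a, tolerance = 1e-8)
  expect_equal(out$pooled[[1]], oracle$z, tolerance = 1e-8)
})

test_that("attention is permutation-equivariant and z is permutation-invariant", {
  ap <- attention_params(attn_dim = 4, embed_dim = 5, n_heads = 2, seed = 9)
  set.seed(31)
  for (r in 1:20) {
    K <- sample(2:10, 1)
    H <- matrix(rnorm(K * 5), K, 5)
    perm <- sample(K)
    a1 <- gated_attention_pool(H, ap)
    a2 <- gated_attention_pool(H[perm, , drop = FALSE], ap)
    expect_equal(a2$weights, a1$weights[perm, , drop = FALSE],
                 tolerance = 1e-12)
    expect_equal(a2$concat, a1$concat, tolerance = 1e-12)
  }
})

test_that("model_forward output invariants and zero-head fixture hold", {
  cfg <- small_config()
  par <- milcox:::init_milcox_params(8, 0, 0, small_config(use_gene = FALSE,
                                                           use_clinical = FALSE))
  # zero out the head: raw outputs (0, 0, s)
  s <- 1.3
  par$Wf <- par$Wf * 0
  par$bf <- c(0, 0, s)
  bag <- matrix(rnorm(40), 5, 8)
  fw <- model_forward(bag, params = par)
  expect_equal(fw$output$p1, 0.5)
  expect_equal(fw$output$p2, 0.5)
  expect_equal(fw$output$t_hat, log1p(exp(s)))
  expect_equal(fw$output$score, 0.25 * log1p(exp(s)))

  # invariants on random parameters and inputs
  par2 <- milcox:::init_milcox_params(8, 0, 0,
                                      small_config(seed = 4, use_gene = FALSE,
                                                   use_clinical = FALSE))
  for (r in 1:10) {
    fw2 <- model_forward(matrix(rnorm(24), 3, 8), params = par2)
    o <- fw2$output
    expect_true(o$p1 > 0 && o$p1 < 1)
    expect_true(o$p2 > 0 && o$p2 < 1)
    expect_gt(o$t_hat, 0)
    expect_equal(o$score, o$p1 * o$p2 * o$t_hat)
    expect_equal(fw2$risk, -log(o$score))
  }
})

test_that("model_forward equals an independent composition of its stages", {
  cfg <- milcox_config(embed_hidden = 4, embed_dim = 3, attn_dim = 3,
                       n_heads = 2, use_gene = TRUE, use_clinical = TRUE,
                       seed = 6)
  par <- milcox:::init_milcox_params(5, 2, 3, cfg)
  X <- matrix(rnorm(20), 4, 5)
  gv <- c(0.3, -0.7); cv <- c(1.1, 0.0, -0.5)
  fw <- model_forward(X, gv, cv, par)

  # straight-line recomposition: embed -> two attention heads -> fusion
  H <- embed_instances(X, par)
  o1 <- brute_gated_attention(H, par$w1, par$U1, par$V1)
  o2 <- brute_gated_attention(H, par$w2, par$U2, par$V2)
  f <- c(o1$z, o2$z, gv, cv)
  r <- drop(par$Wf %*% f) + par$bf
  p1 <- 1 / (1 + exp(-r[1])); p2 <- 1 / (1 + exp(-r[2]))
  th <- log1p(exp(r[3]))
  expect_equal(fw$output$score, p1 * p2 * th, tolerance = 1e-6)
  expect_equal(fw$risk, -log(p1 * p2 * th), tolerance = 1e-6)

  # modality dimension checks
  expect_error(model_forward(X, NULL, cv, par), "missing gene")
  expect_error(model_forward(X, c(1, 2, 3), cv, par), "length")
})

test_that("Cox loss has the right values, invariances and gradient", {
  # two patients, event at the earlier time, equal risks: log(2)
  expect_equal(cox_nll(c(0.7, 0.7), c(1, 2), c(1, 0)), log(2))

  # shift invariance
  set.seed(8)
  eta <- rnorm(10); tm <- rexp(10); ev <- rbinom(10, 1, 0.6)
  ev[1] <- 1
  expect_equal(cox_nll(eta + 3.7, tm, ev), cox_nll(eta, tm, ev),
               tolerance = 1e-12)

  # loss strictly decreases when an event patient's risk increases
  i <- which(ev == 1)[1]
  eta2 <- eta; eta2[i] <- eta2[i] + 0.5
  expect_lt(cox_nll(eta2, tm, ev), cox_nll(eta, tm, ev))

  # analytic gradient vs central finite differences
  g <- cox_nll_grad(eta, tm, ev)
  for (j in 1:10) {
    h <- 1e-6
    ep <- eta; ep[j] <- ep[j] + h
    em <- eta; em[j] <- em[j] - h
    fd <- (cox_nll(ep, tm, ev) - cox_nll(em, tm, ev)) / (2 * h)
    expect_equal(g[j], fd, tolerance = 1e-5)
  }

  expect_warning(l0 <- cox_nll(eta, tm, rep(0, 10)), "no events")
  expect_equal(l0, 0)
})

test_that("full-network analytic gradient matches finite differences", {
  co <- small_cohort(seed = 3)
  cfg <- milcox_config(embed_hidden = 4, embed_dim = 3, attn_dim = 3,
                       dropout = 0, batch_size = 8, seed = 1)
  inp <- milcox:::prepare_inputs(co, cfg)
  par <- milcox:::init_milcox_params(inp$D, inp$gene_dim, inp$clin_dim, cfg)
  idx <- 1:8
  fwd <- function(p, i) milcox:::forward_patient(p, inp$bags[[i]],
                                                 inp$gene[i, ],
                                                 inp$clinical[i, ])
  etas <- vapply(idx, function(i) fwd(par, i)$eta, numeric(1))
  detas <- cox_nll_grad(etas, inp$patients$time[idx],
                        inp$patients$event[idx])
  grad <- milcox:::zeros_like(par)
  for (k in seq_along(idx)) {
    grad <- milcox:::backward_patient(par, fwd(par, idx[k])$cache,
                                      detas[k], grad)
  }
  lossfn <- function(p) {
    e <- vapply(idx, function(i) fwd(p, i)$eta, numeric(1))
    cox_nll(e, inp$patients$time[idx], inp$patients$event[idx])
  }
  set.seed(2)
  for (nm in names(par)) {
    for (j in sample(length(par[[nm]]), min(3, length(par[[nm]])))) {
      h <- 1e-5
      pp <- par; pp[[nm]][j] <- pp[[nm]][j] + h
      pm <- par; pm[[nm]][j] <- pm[[nm]][j] - h
      fd <- (lossfn(pp) - lossfn(pm)) / (2 * h)
      expect_equal(grad[[nm]][j], fd, tolerance = 1e-4,
                   label = sprintf("d loss / d %s[%d]", nm, j))
    }
  }
})

test_that("training is deterministic under a fixed seed", {
  co <- small_cohort(seed = 3)
  cfg <- small_config(seed = 1, epochs = 3)
  f1 <- milcox(co, cfg)
  f2 <- milcox(co, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)

  # a different seed gives a different trajectory
  f3 <- milcox(co, small_config(seed = 2, epochs = 3))
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))
})

test_that("training records history and honours option flags", {
  co <- small_cohort(seed = 3)
  fit <- milcox(co, small_config(epochs = 4))
  expect_equal(nrow(fit$history), 4)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_length(intersect(fit$train_idx, fit$val_idx), 0)
  expect_equal(sort(c(fit$train_idx, fit$val_idx)), 1:40)

  # weighted sampling and sgd run end-to-end
  fit2 <- milcox(co, small_config(epochs = 2, weighted_sample = TRUE,
                                  optimizer = "sgd"))
  expect_equal(nrow(fit2$history), 2)

  # no-event cohort is rejected before training
  co0 <- co
  co0$patients$event <- rep(0L, 40)
  expect_error(milcox(co0, small_config()), "events")
})

test_that("prediction is batch-independent, order-equivariant and matches model_forward", {
  co <- small_cohort(seed = 3)
  fit <- milcox(co, small_config(epochs = 2))
  pr <- predict(fit, co)
  expect_equal(nrow(pr), 40)
  expect_equal(pr$score, pr$p1 * pr$p2 * pr$t_hat)

  # permuting patients permutes rows identically
  perm <- sample(40)
  cop <- subset_cohort(co, perm)
  prp <- predict(fit, cop)
  expect_equal(prp$risk, pr$risk[perm], tolerance = 1e-12)

  # single-patient prediction equals the batched row
  co1 <- subset_cohort(co, 7)
  pr1 <- predict(fit, co1)
  expect_equal(pr1$risk, pr$risk[7], tolerance = 1e-12)

  # and equals a direct model_forward call with standardized inputs
  inp <- milcox:::prepare_inputs_for_predict(fit, co)
  fw <- model_forward(inp$bags[[7]], inp$gene[7, ], inp$clinical[7, ],
                      fit$params)
  expect_equal(fw$risk, pr$risk[7])

  # risk ranking is the reverse of score ranking
  expect_equal(order(pr$risk), rev(order(pr$score)))
})

test_that("model methods and persistence round-trip", {
  co <- small_cohort(seed = 3)
  fit <- milcox(co, small_config(epochs = 2))
  expect_output(print(fit), "attention-MIL")
  sm <- summary(fit, co)
  expect_output(print(sm), "concordance")
  expect_true(is.matrix(coef(fit)))

  res <- residuals(fit, co)
  expect_length(res, 40)
  expect_true(all(res <= 1))

  tmp <- tempfile(fileext = ".json")
  save_milcox(fit, tmp)
  fit2 <- load_milcox(tmp)
  pr1 <- predict(fit, co); pr2 <- predict(fit2, co)
  expect_equal(pr1$risk, pr2$risk, tolerance = 1e-12)
})

test_that("cross-validation produces per-fold held-out concordance", {
  co <- small_cohort(seed = 5, n = 60)
  cfg <- small_config(epochs = 2, k_folds = 3)
  cvr <- milcox_cv(co, cfg)
  expect_length(cvr, 3)
  folds <- vapply(cvr, `[[`, integer(1), "fold")
  expect_equal(folds, 1:3)
  cis <- vapply(cvr, `[[`, numeric(1), "c_index")
  expect_true(all(is.finite(cis)))
  # fold restriction
  cfg2 <- small_config(epochs = 2, k_folds = 3, k_start = 2, k_end = 2)
  cvr2 <- milcox_cv(co, cfg2)
  expect_length(cvr2, 1)
  expect_equal(cvr2[[1]]$fold, 2)
})
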