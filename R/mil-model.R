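#' Training configuration for the multimodal MIL survival model
#'
#' Defaults follow the reference training recipe: Adam, learning rate
#' 1e-4, weight decay 1e-5, 30 epochs, dropout 0.25, seed 1, 10-fold
#' cross-validation available, and an 8:2 train/validation split.
#'
#' @param max_epochs Training epochs (default 30).
#' @param learning_rate Optimizer step size (default 1e-4).
#' @param weight_decay L2 penalty coupled into the gradient
#'   (default 1e-5).
#' @param optimizer `"adam"` or `"sgd"` (default `"adam"`).
#' @param dropout Dropout rate applied after each embedding layer during
#'   training (default 0.25).
#' @param seed RNG seed controlling initialization, splits, shuffling
#'   and dropout (default 1).
#' @param k_folds Folds for [milcox_cv()] (default 10).
#' @param k_start,k_end First/last fold to run; `-1` means all folds.
#' @param early_stopping Stop on stagnating validation loss
#'   (default FALSE).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param weighted_sample Inverse-frequency sampling by event status
#'   when forming batches (default FALSE).
#' @param use_gene,use_clinical Include the gene / clinical modality in
#'   the fusion input (default TRUE).
#' @param val_fraction Validation share of the split (default 0.2,
#'   i.e. 8:2).
#' @param batch_size Patients per optimization step (default 32).
#' @param embed_hidden,embed_dim Hidden and output width of the
#'   two-layer instance embedder (defaults 512 and 256).
#' @param attn_dim Attention gate width L (default 128).
#' @param n_heads Parallel gated-attention heads (default 2).
#' @return An object of class `milcox_config`.
#' @export
milcox_config <- function(max_epochs = 30L, learning_rate = 1e-4,
                          weight_decay = 1e-5,
                          optimizer = c("adam", "sgd"),
                          dropout = 0.25, seed = 1L,
                          k_folds = 10L, k_start = -1L, k_end = -1L,
                          early_stopping = FALSE, patience = 5L,
                          weighted_sample = FALSE,
                          use_gene = TRUE, use_clinical = TRUE,
                          val_fraction = 0.2, batch_size = 32L,
                          embed_hidden = 512L, embed_dim = 256L,
                          attn_dim = 128L, n_heads = 2L) {
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (k_folds < 2L) stop("k_folds must be >= 2")
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("val_fraction must lie in (0, 1)")
  }
  out <- list(max_epochs = as.integer(max_epochs),
              learning_rate = learning_rate, weight_decay = weight_decay,
              optimizer = optimizer, dropout = dropout,
              seed = as.integer(seed), k_folds = as.integer(k_folds),
              k_start = as.integer(k_start), k_end = as.integer(k_end),
              early_stopping = isTRUE(early_stopping),
              patience = as.integer(patience),
              weighted_sample = isTRUE(weighted_sample),
              use_gene = isTRUE(use_gene),
              use_clinical = isTRUE(use_clinical),
              val_fraction = val_fraction,
              batch_size = as.integer(batch_size),
              embed_hidden = as.integer(embed_hidden),
              embed_dim = as.integer(embed_dim),
              attn_dim = as.integer(attn_dim),
              n_heads = as.integer(n_heads))
  class(out) <- "milcox_config"
  out
}

#' Read a training configuration from JSON
#'
#' Accepts the flat key set used by the command-line interface
#' (`max_epochs`, `lr`, `weight_decay`, `seed`, `k`, `k_start`, `k_end`,
#' `early_stopping`, `opt`, `drop_out`, `weighted_sample`, `gene`,
#' `cli`, plus any [milcox_config] argument name).
#'
#' @param path Path to a JSON file.
#' @return A [milcox_config].
#' @export
read_train_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  alias <- c(lr = "learning_rate", k = "k_folds", opt = "optimizer",
             drop_out = "dropout", gene = "use_gene", cli = "use_clinical")
  for (a in names(alias)) {
    if (!is.null(j[[a]])) { j[[alias[[a]]]] <- j[[a]]; j[[a]] <- NULL }
  }
  for (drop in c("results_dir", "split_dir", "log_data", "exp_code", "task",
                 "data_root_dir")) j[[drop]] <- NULL
  do.call(milcox_config, j)
}

# ---- numerics ---------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
relu <- function(x) pmax(x, 0)

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# ---- parameter containers ---------------------------------------------

#' Initialize gated-attention parameters
#'
#' He-style normal initialization of the gate parameters `w` (length L)
#' and `U`, `V` (L x M) for each head.
#'
#' @param attn_dim Gate width L.
#' @param embed_dim Instance embedding width M.
#' @param n_heads Number of parallel heads (default 2).
#' @param seed RNG seed.
#' @return List of class `attention_params` with one
#'   `list(w, U, V)` per head.
#' @export
attention_params <- function(attn_dim, embed_dim, n_heads = 2L, seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  heads <- lapply(seq_len(n_heads), function(h) {
    list(w = stats::rnorm(attn_dim, sd = sqrt(2 / attn_dim)),
         U = matrix(stats::rnorm(attn_dim * embed_dim,
                                 sd = sqrt(2 / embed_dim)),
                    attn_dim, embed_dim),
         V = matrix(stats::rnorm(attn_dim * embed_dim,
                                 sd = sqrt(2 / embed_dim)),
                    attn_dim, embed_dim))
  })
  structure(list(heads = heads, attn_dim = as.integer(attn_dim),
                 embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads)),
            class = "attention_params")
}

init_milcox_params <- function(D, gene_dim, clin_dim, cfg) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  h <- cfg$embed_hidden; M <- cfg$embed_dim; L <- cfg$attn_dim
  fdim <- cfg$n_heads * M + gene_dim + clin_dim
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nc)),
                                nr, nc)
  # small positive biases keep rectified units alive at initialization
  par <- list(W1 = he(h, D), b1 = rep(0.01, h),
              W2 = he(M, h), b2 = rep(0.01, M),
              Wf = he(3L, fdim) * 0.1, bf = numeric(3L))
  for (j in seq_len(cfg$n_heads)) {
    par[[paste0("V", j)]] <- he(L, M)
    par[[paste0("U", j)]] <- he(L, M)
    par[[paste0("w", j)]] <- stats::rnorm(L, sd = sqrt(2 / L))
  }
  attr(par, "dims") <- list(D = D, hidden = h, M = M, L = L,
                            n_heads = cfg$n_heads,
                            gene_dim = gene_dim, clin_dim = clin_dim)
  par
}

zeros_like <- function(par) {
  g <- lapply(par, function(p) if (is.matrix(p)) p * 0 else numeric(length(p)))
  attributes(g) <- attributes(par)
  g
}

# ---- exported building blocks -----------------------------------------

#' Embed a bag of instance features
#'
#' Applies the two-layer rectified embedder independently to each
#' instance: `H_k = relu(W2 relu(W1 x_k + b1) + b2)`.  Dropout is only
#' active in training mode inside the fitter; this user-facing function
#' always evaluates deterministically.
#'
#' @param features K x D matrix of instance features (or a [patch_bag]).
#' @param params List with `W1` (h x D), `b1`, `W2` (M x h), `b2`.
#' @return K x M matrix of embedded instances.
#' @export
embed_instances <- function(features, params) {
  X <- if (inherits(features, "patch_bag")) features$features else
    as.matrix(features)
  if (ncol(X) != ncol(params$W1)) {
    stop(sprintf("feature dimension %d does not match embedder input %d",
                 ncol(X), ncol(params$W1)))
  }
  Z1 <- relu(sweep(X %*% t(params$W1), 2, params$b1, "+"))
  relu(sweep(Z1 %*% t(params$W2), 2, params$b2, "+"))
}

#' Gated-attention pooling of an embedded bag
#'
#' For each head, instance k receives the gate logit
#' `w' (tanh(V h_k) * sigm(U h_k))`; a softmax over the bag turns the
#' logits into attention weights `a` summing to one, and the pooled
#' representation is the weighted average `z = sum_k a_k h_k`.  With
#' several heads the pooled vectors are concatenated.
#'
#' @param H K x M matrix of embedded instances (K >= 1).
#' @param params An [attention_params] object, or a single
#'   `list(w, U, V)` head.
#' @return List of class `attention_output`: `weights` (K x n_heads
#'   matrix, columns summing to 1), `pooled` (list of length-M vectors
#'   per head), `concat` (concatenated pooled vector).
#' @export
gated_attention_pool <- function(H, params) {
  H <- as.matrix(H)
  if (nrow(H) < 1L) stop("bag must contain at least one instance")
  heads <- if (!is.null(params$heads)) params$heads else list(params)
  K <- nrow(H)
  weights <- matrix(NA_real_, K, length(heads))
  pooled <- vector("list", length(heads))
  for (j in seq_along(heads)) {
    hd <- heads[[j]]
    gate <- tanh(H %*% t(hd$V)) * sigmoid(H %*% t(hd$U))
    a <- softmax(drop(gate %*% hd$w))
    weights[, j] <- a
    pooled[[j]] <- drop(crossprod(H, a))
  }
  structure(list(weights = weights, pooled = pooled,
                 concat = unlist(pooled)),
            class = "attention_output")
}

#' Cox partial-likelihood loss
#'
#' Negative log Breslow partial likelihood of risk scores, averaged over
#' events:
#' `-(1/E) sum_{i: event} [eta_i - log sum_{j: t_j >= t_i} exp(eta_j)]`.
#' Invariant to adding a constant to all risks.  With zero events the
#' loss is defined as 0 with a warning.
#'
#' @param risks Per-patient log-hazard risk scores.
#' @param time Follow-up times.
#' @param event 0/1 event indicators.
#' @return The scalar loss.
#' @seealso [cox_nll_grad()] for the analytic gradient.
#' @export
cox_nll <- function(risks, time, event) {
  if (!all(is.finite(risks))) stop("risks must be finite")
  event <- as.integer(event)
  E <- sum(event)
  if (E == 0L) { warning("no events: loss is 0"); return(0) }
  eta <- risks - max(risks)
  w <- exp(eta)
  ll <- 0
  for (i in which(event == 1L)) {
    ll <- ll + eta[i] - log(sum(w[time >= time[i]]))
  }
  -ll / E
}

#' Gradient of the Cox partial-likelihood loss
#'
#' @inheritParams cox_nll
#' @return Vector `d loss / d risks` of the same length as `risks`.
#' @export
cox_nll_grad <- function(risks, time, event) {
  event <- as.integer(event)
  E <- sum(event)
  n <- length(risks)
  if (E == 0L) return(numeric(n))
  eta <- risks - max(risks)
  w <- exp(eta)
  g <- numeric(n)
  # accumulate sum over event times t_i <= t_j of 1/S(t_i) per patient j
  inv_s_cum <- numeric(n)
  for (i in which(event == 1L)) {
    at_risk <- time >= time[i]
    inv_s_cum[at_risk] <- inv_s_cum[at_risk] + 1 / sum(w[at_risk])
  }
  -(event - w * inv_s_cum) / E
}

# ---- forward / backward -----------------------------------------------

# One patient's forward pass with cached intermediates for backprop.
# drop1/drop2: pre-scaled dropout masks (NULL in evaluation mode).
forward_patient <- function(par, X, gene_vec, clin_vec,
                            drop1 = NULL, drop2 = NULL) {
  dims <- attr(par, "dims")
  A1 <- sweep(X %*% t(par$W1), 2, par$b1, "+")
  Z1 <- relu(A1)
  if (!is.null(drop1)) Z1 <- Z1 * drop1
  A2 <- sweep(Z1 %*% t(par$W2), 2, par$b2, "+")
  H <- relu(A2)
  if (!is.null(drop2)) H <- H * drop2

  K <- nrow(X)
  heads <- vector("list", dims$n_heads)
  zs <- vector("list", dims$n_heads)
  for (j in seq_len(dims$n_heads)) {
    V <- par[[paste0("V", j)]]; U <- par[[paste0("U", j)]]
    w <- par[[paste0("w", j)]]
    Tm <- tanh(H %*% t(V))
    Sm <- sigmoid(H %*% t(U))
    Gm <- Tm * Sm
    a <- softmax(drop(Gm %*% w))
    heads[[j]] <- list(Tm = Tm, Sm = Sm, Gm = Gm, a = a)
    zs[[j]] <- drop(crossprod(H, a))
  }
  f <- c(unlist(zs), gene_vec, clin_vec)
  r <- drop(par$Wf %*% f) + par$bf
  p1 <- sigmoid(r[1]); p2 <- sigmoid(r[2]); th <- softplus(r[3])
  eta <- -(log(p1) + log(p2) + log(th))
  list(eta = eta,
       output = list(p1 = p1, p2 = p2, t_hat = th, score = p1 * p2 * th),
       attention = structure(
         list(weights = vapply(heads, `[[`, numeric(K), "a"),
              pooled = zs, concat = unlist(zs)),
         class = "attention_output"),
       cache = list(X = X, A1 = A1, Z1 = Z1, A2 = A2, H = H,
                    heads = heads, zs = zs, f = f, r = r,
                    p1 = p1, p2 = p2, th = th,
                    drop1 = drop1, drop2 = drop2))
}

# Accumulate parameter gradients for one patient given d loss / d eta.
backward_patient <- function(par, cache, d_eta, grad) {
  dims <- attr(par, "dims")
  M <- dims$M
  dr <- c(d_eta * -(1 - cache$p1),
          d_eta * -(1 - cache$p2),
          d_eta * -(sigmoid(cache$r[3]) / cache$th))
  grad$Wf <- grad$Wf + outer(dr, cache$f)
  grad$bf <- grad$bf + dr
  df <- drop(crossprod(par$Wf, dr))

  H <- cache$H
  dH <- matrix(0, nrow(H), M)
  for (j in seq_len(dims$n_heads)) {
    hd <- cache$heads[[j]]
    V <- par[[paste0("V", j)]]; U <- par[[paste0("U", j)]]
    w <- par[[paste0("w", j)]]
    dz <- df[((j - 1) * M + 1):(j * M)]
    a <- hd$a
    dH <- dH + outer(a, dz)
    da <- drop(H %*% dz)
    dl <- a * (da - sum(a * da))
    dG <- outer(dl, w)
    dT <- dG * hd$Sm
    dS <- dG * hd$Tm
    dPreV <- dT * (1 - hd$Tm^2)
    dPreU <- dS * hd$Sm * (1 - hd$Sm)
    grad[[paste0("V", j)]] <- grad[[paste0("V", j)]] + crossprod(dPreV, H)
    grad[[paste0("U", j)]] <- grad[[paste0("U", j)]] + crossprod(dPreU, H)
    grad[[paste0("w", j)]] <- grad[[paste0("w", j)]] +
      drop(crossprod(hd$Gm, dl))
    dH <- dH + dPreV %*% V + dPreU %*% U
  }
  if (!is.null(cache$drop2)) dH <- dH * cache$drop2
  dA2 <- dH * (cache$A2 > 0)
  grad$W2 <- grad$W2 + crossprod(dA2, cache$Z1)
  grad$b2 <- grad$b2 + colSums(dA2)
  dZ1 <- dA2 %*% par$W2
  if (!is.null(cache$drop1)) dZ1 <- dZ1 * cache$drop1
  dA1 <- dZ1 * (cache$A1 > 0)
  grad$W1 <- grad$W1 + crossprod(dA1, cache$X)
  grad$b1 <- grad$b1 + colSums(dA1)
  grad
}

#' Forward pass of the multimodal MIL survival network
#'
#' Embeds a bag, pools it with gated attention, concatenates the pooled
#' heads with the gene and clinical covariate vectors, and maps the
#' fusion vector through the final fully connected head to three
#' outputs: two survival probabilities (`p1`, `p2`, logistic-squashed)
#' and a survival-time estimate (`t_hat`, softplus-squashed, months).
#' The survival score is their product; the training risk is
#' `-log(score)`.
#'
#' @param bag A [patch_bag] or K x D feature matrix.
#' @param gene_vec Numeric gene covariate vector (`NULL` when the gene
#'   modality is off).
#' @param clinical_vec Numeric clinical covariate vector (`NULL` when
#'   the clinical modality is off).
#' @param params Parameter list created by the fitter (or
#'   `init_milcox_params`).
#' @return List with `output` (`p1`, `p2`, `t_hat`, `score`), `risk`
#'   (`-log(score)`), and `attention` (an `attention_output`).
#' @export
model_forward <- function(bag, gene_vec = NULL, clinical_vec = NULL,
                          params) {
  dims <- attr(params, "dims")
  X <- if (inherits(bag, "patch_bag")) bag$features else as.matrix(bag)
  if (ncol(X) != dims$D) {
    stop(sprintf("bag feature dimension %d; model expects %d",
                 ncol(X), dims$D))
  }
  gv <- check_modality(gene_vec, dims$gene_dim, "gene")
  cv <- check_modality(clinical_vec, dims$clin_dim, "clinical")
  fw <- forward_patient(params, X, gv, cv)
  list(output = fw$output, risk = fw$eta, attention = fw$attention)
}

check_modality <- function(vec, dim_needed, label) {
  if (dim_needed == 0L) {
    if (!is.null(vec) && length(vec) > 0) {
      stop(sprintf("model was configured without the %s modality", label))
    }
    return(numeric(0))
  }
  if (is.null(vec)) stop(sprintf("missing %s covariate vector", label))
  if (length(vec) != dim_needed) {
    stop(sprintf("%s vector has length %d; model expects %d",
                 label, length(vec), dim_needed))
  }
  as.numeric(vec)
}

# ---- optimizer --------------------------------------------------------

adam_state <- function(par) {
  list(m = zeros_like(par), v = zeros_like(par), t = 0L)
}

optimizer_step <- function(par, grad, state, cfg) {
  wd <- cfg$weight_decay; lr <- cfg$learning_rate
  if (cfg$optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$t <- state$t + 1L
    for (nm in names(par)) {
      g <- grad[[nm]] + wd * par[[nm]]
      state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
      state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
      mhat <- state$m[[nm]] / (1 - b1^state$t)
      vhat <- state$v[[nm]] / (1 - b2^state$t)
      par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  } else {
    for (nm in names(par)) {
      par[[nm]] <- par[[nm]] - lr * (grad[[nm]] + wd * par[[nm]])
    }
  }
  list(par = par, state = state)
}

# ---- the fitter -------------------------------------------------------

#' Fit the multimodal attention-MIL Cox survival model
#'
#' Trains the full network — instance embedder, gated-attention pooling,
#' multimodal fusion, three-output survival head — by minimizing the
#' Cox partial-likelihood loss of the risk `-log(p1 * p2 * t_hat)` with
#' the configured optimizer, on a seeded 8:2 train/validation split of
#' the cohort.  All randomness (initialization, split, shuffling,
#' dropout) derives from `config$seed`, so identical inputs reproduce
#' identical histories.
#'
#' @param cohort A `synthetic_cohort` or a list with elements
#'   `patients` (a [surv_data]), `bags` (list of [patch_bag]s aligned
#'   with patients), and optionally `expression` (genes x patients) and
#'   `clinical` (patients x covariates).
#' @param config A [milcox_config].
#' @param gene_panel Optional character vector restricting the gene
#'   modality to a screened panel (default: all rows of
#'   `cohort$expression`).
#' @return An object of class `milcox`: the trained parameters, the
#'   per-epoch loss `history`, the split indices, modality
#'   standardization constants and the config.
#' @seealso [predict.milcox()], [milcox_cv()]
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 30, feature_dim = 8,
#'                                   bag_size_range = c(4, 6), n_genes = 10))
#' cfg <- milcox_config(max_epochs = 2, embed_hidden = 8, embed_dim = 4,
#'                      attn_dim = 4, batch_size = 10)
#' fit <- milcox(co, cfg)
#' print(fit)
#' @export
milcox <- function(cohort, config = milcox_config(), gene_panel = NULL) {
  inp <- prepare_inputs(cohort, config, gene_panel)
  cfg <- config
  n <- nrow(inp$patients)
  if (sum(inp$patients$event) < 2L) stop("need at least 2 events to train")

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)

  # seeded 8:2 split
  n_val <- max(1L, round(cfg$val_fraction * n))
  val_idx <- sort(sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (sum(inp$patients$event[tr_idx]) < 2L) {
    stop("training split holds fewer than 2 events")
  }

  par <- init_milcox_params(inp$D, inp$gene_dim, inp$clin_dim, cfg)
  state <- adam_state(par)
  hist_tr <- hist_val <- numeric(0)
  best <- list(loss = Inf, par = par, epoch = 0L)
  bad_epochs <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    order_idx <- if (cfg$weighted_sample) {
      ev <- inp$patients$event[tr_idx]
      wts <- ifelse(ev == 1L, 1 / max(mean(ev), 1e-12),
                    1 / max(1 - mean(ev), 1e-12))
      sample(tr_idx, length(tr_idx), replace = TRUE, prob = wts)
    } else {
      sample(tr_idx)
    }
    nb <- ceiling(length(order_idx) / cfg$batch_size)
    for (b in seq_len(nb)) {
      ids <- order_idx[((b - 1L) * cfg$batch_size + 1L):
                         min(b * cfg$batch_size, length(order_idx))]
      if (sum(inp$patients$event[ids]) == 0L) next
      caches <- vector("list", length(ids))
      etas <- numeric(length(ids))
      for (k in seq_along(ids)) {
        i <- ids[k]
        d1 <- d2 <- NULL
        if (cfg$dropout > 0) {
          K <- nrow(inp$bags[[i]])
          d1 <- matrix(stats::rbinom(K * inp$hdim, 1, 1 - cfg$dropout),
                       K, inp$hdim) / (1 - cfg$dropout)
          d2 <- matrix(stats::rbinom(K * cfg$embed_dim, 1, 1 - cfg$dropout),
                       K, cfg$embed_dim) / (1 - cfg$dropout)
        }
        fw <- forward_patient(par, inp$bags[[i]], inp$gene[i, ],
                              inp$clinical[i, ], d1, d2)
        caches[[k]] <- fw$cache
        etas[k] <- fw$eta
      }
      detas <- cox_nll_grad(etas, inp$patients$time[ids],
                            inp$patients$event[ids])
      grad <- zeros_like(par)
      for (k in seq_along(ids)) {
        if (detas[k] != 0) grad <- backward_patient(par, caches[[k]],
                                                    detas[k], grad)
      }
      upd <- optimizer_step(par, grad, state, cfg)
      par <- upd$par; state <- upd$state
    }
    # evaluation-mode losses
    eta_all <- eval_etas(par, inp, seq_len(n))
    hist_tr <- c(hist_tr, cox_nll(eta_all[tr_idx],
                                  inp$patients$time[tr_idx],
                                  inp$patients$event[tr_idx]))
    lv <- if (sum(inp$patients$event[val_idx]) > 0) {
      cox_nll(eta_all[val_idx], inp$patients$time[val_idx],
              inp$patients$event[val_idx])
    } else NA_real_
    hist_val <- c(hist_val, lv)
    if (is.finite(lv) && lv < best$loss) {
      best <- list(loss = lv, par = par, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
    }
    if (cfg$early_stopping && bad_epochs >= cfg$patience) break
  }
  final_par <- if (cfg$early_stopping && is.finite(best$loss)) best$par
               else par

  out <- list(params = final_par, config = cfg,
              history = data.frame(epoch = seq_along(hist_tr),
                                   train_loss = hist_tr,
                                   val_loss = hist_val),
              train_idx = tr_idx, val_idx = val_idx,
              gene_panel = inp$gene_panel,
              standardize = inp$standardize,
              dims = attr(final_par, "dims"),
              n = n, n_events = sum(inp$patients$event),
              best_epoch = best$epoch,
              patients = inp$patients)
  class(out) <- "milcox"
  out
}

# Assemble aligned per-patient model inputs from a cohort-like list.
prepare_inputs <- function(cohort, cfg, gene_panel = NULL) {
  patients <- as_surv_data(cohort$patients)
  n <- nrow(patients)
  bags <- lapply(cohort$bags, function(b) {
    if (inherits(b, "patch_bag")) b$features
    else if (is.list(b)) combine_bags(b)$features
    else as.matrix(b)
  })
  if (length(bags) != n) stop("one bag (or bag list) per patient required")
  D <- ncol(bags[[1]])
  if (any(vapply(bags, ncol, integer(1)) != D)) {
    stop("bags differ in feature dimension")
  }

  std <- list()
  if (cfg$use_gene) {
    if (is.null(cohort$expression)) stop("gene modality on but no expression")
    expr <- as.matrix(cohort$expression)
    if (is.null(gene_panel)) gene_panel <- rownames(expr)
    missing <- setdiff(gene_panel, rownames(expr))
    if (length(missing) > 0) stop("gene panel absent from expression matrix")
    gm <- t(expr[gene_panel, patients$patient_id, drop = FALSE])
    ctr <- colMeans(gm); scl <- apply(gm, 2, stats::sd); scl[scl == 0] <- 1
    gene <- sweep(sweep(gm, 2, ctr), 2, scl, "/")
    std$gene_center <- ctr; std$gene_scale <- scl
  } else {
    gene <- matrix(numeric(0), n, 0)
    gene_panel <- character(0)
  }
  if (cfg$use_clinical) {
    if (is.null(cohort$clinical)) stop("clinical modality on but no clinical")
    cm <- as.matrix(cohort$clinical)[patients$patient_id, , drop = FALSE]
    ctr <- colMeans(cm); scl <- apply(cm, 2, stats::sd); scl[scl == 0] <- 1
    clinical <- sweep(sweep(cm, 2, ctr), 2, scl, "/")
    std$clin_center <- ctr; std$clin_scale <- scl
  } else {
    clinical <- matrix(numeric(0), n, 0)
  }
  list(patients = patients, bags = bags, gene = gene, clinical = clinical,
       D = D, hdim = cfg$embed_hidden, gene_dim = ncol(gene),
       clin_dim = ncol(clinical), gene_panel = gene_panel,
       standardize = std)
}

eval_etas <- function(par, inp, idx) {
  vapply(idx, function(i) {
    forward_patient(par, inp$bags[[i]], inp$gene[i, ], inp$clinical[i, ])$eta
  }, numeric(1))
}

# ---- methods ----------------------------------------------------------

#' Predict survival outputs for a cohort
#'
#' Deterministic evaluation-mode forward pass per patient (dropout off);
#' outputs do not depend on batch composition or patient order.
#'
#' @param object A fitted [milcox] model.
#' @param newdata A cohort-like list (`patients`, `bags`, and the
#'   modalities the model was trained with).  Defaults to signalling an
#'   error: prediction always needs data.
#' @param ... Unused.
#' @return Data frame with one row per patient: `patient_id`, `p1`,
#'   `p2`, `t_hat`, `score` (= p1 * p2 * t_hat) and `risk`
#'   (= -log(score); higher means worse prognosis).
#' @export
predict.milcox <- function(object, newdata, ...) {
  if (missing(newdata)) stop("newdata is required")
  inp <- prepare_inputs_for_predict(object, newdata)
  n <- nrow(inp$patients)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fw <- forward_patient(object$params, inp$bags[[i]], inp$gene[i, ],
                          inp$clinical[i, ])
    rows[[i]] <- data.frame(patient_id = inp$patients$patient_id[i],
                            p1 = fw$output$p1, p2 = fw$output$p2,
                            t_hat = fw$output$t_hat,
                            score = fw$output$score, risk = fw$eta,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# apply the training-time standardization to new data
prepare_inputs_for_predict <- function(object, cohort) {
  patients <- as_surv_data(cohort$patients)
  n <- nrow(patients)
  bags <- lapply(cohort$bags, function(b) {
    if (inherits(b, "patch_bag")) b$features
    else if (is.list(b)) combine_bags(b)$features
    else as.matrix(b)
  })
  if (length(bags) != n) stop("one bag per patient required")
  dims <- object$dims
  if (ncol(bags[[1]]) != dims$D) {
    stop(sprintf("bag feature dimension %d; model expects %d",
                 ncol(bags[[1]]), dims$D))
  }
  if (dims$gene_dim > 0) {
    if (is.null(cohort$expression)) stop("model needs the gene modality")
    gm <- t(as.matrix(cohort$expression)[object$gene_panel,
                                         patients$patient_id, drop = FALSE])
    gene <- sweep(sweep(gm, 2, object$standardize$gene_center), 2,
                  object$standardize$gene_scale, "/")
  } else gene <- matrix(numeric(0), n, 0)
  if (dims$clin_dim > 0) {
    if (is.null(cohort$clinical)) stop("model needs the clinical modality")
    cm <- as.matrix(cohort$clinical)[patients$patient_id, , drop = FALSE]
    clinical <- sweep(sweep(cm, 2, object$standardize$clin_center), 2,
                      object$standardize$clin_scale, "/")
  } else clinical <- matrix(numeric(0), n, 0)
  list(patients = patients, bags = bags, gene = gene, clinical = clinical)
}

#' @export
print.milcox <- function(x, ...) {
  d <- x$dims
  cat("Multimodal attention-MIL Cox survival model\n")
  cat(sprintf("  instance features %d -> %d -> %d, %d attention heads (L = %d)\n",
              d$D, d$hidden, d$M, d$n_heads, d$L))
  cat(sprintf("  modalities: image%s%s; fusion input %d\n",
              if (d$gene_dim > 0) sprintf(" + %d genes", d$gene_dim) else "",
              if (d$clin_dim > 0) sprintf(" + %d clinical", d$clin_dim) else "",
              d$n_heads * d$M + d$gene_dim + d$clin_dim))
  cat(sprintf("  trained %d epochs on %d patients (%d events); final val loss %.4f\n",
              nrow(x$history), x$n, x$n_events,
              utils::tail(x$history$val_loss, 1)))
  invisible(x)
}

#' Summary of a fitted model
#'
#' Reports the architecture, loss trajectory and — when the training
#' cohort is supplied — train/validation concordance of the risk score.
#'
#' @param object A fitted [milcox].
#' @param cohort The cohort used for fitting (optional).
#' @param ... Unused.
#' @export
summary.milcox <- function(object, cohort = NULL, ...) {
  out <- list(dims = object$dims, history = object$history,
              n = object$n, n_events = object$n_events)
  if (!is.null(cohort)) {
    pr <- predict(object, cohort)
    out$c_index_train <- concordance_index(
      pr$risk[object$train_idx], object$patients[object$train_idx, ])
    out$c_index_val <- concordance_index(
      pr$risk[object$val_idx], object$patients[object$val_idx, ])
  }
  class(out) <- "summary.milcox"
  out
}

#' @export
print.summary.milcox <- function(x, ...) {
  cat(sprintf("milcox model: %d patients, %d events, %d epochs\n",
              x$n, x$n_events, nrow(x$history)))
  cat(sprintf("  final train loss %.4f, val loss %.4f\n",
              utils::tail(x$history$train_loss, 1),
              utils::tail(x$history$val_loss, 1)))
  if (!is.null(x$c_index_train)) {
    cat(sprintf("  concordance: train %.3f, validation %.3f\n",
                x$c_index_train, x$c_index_val))
  }
  invisible(x)
}

#' @export
coef.milcox <- function(object, ...) {
  object$params$Wf
}

#' Plot the training history
#'
#' @param x A fitted [milcox].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.milcox <- function(x, ...) {
  graphics::matplot(x$history$epoch,
                    cbind(x$history$train_loss, x$history$val_loss),
                    type = "l", lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "Cox partial-likelihood loss",
                    ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' Martingale residuals of a fitted model
#'
#' `r_i = event_i - Lambda0(t_i) * exp(risk_i - mean(risk))` with the
#' Breslow baseline cumulative hazard.
#'
#' @param object A fitted [milcox].
#' @param cohort The cohort to evaluate on.
#' @param ... Unused.
#' @export
residuals.milcox <- function(object, cohort, ...) {
  pr <- predict(object, cohort)
  data <- as_surv_data(cohort$patients)
  eta <- pr$risk - mean(pr$risk)
  w <- exp(eta)
  ch0 <- vapply(data$time, function(tt) {
    et <- unique(data$time[data$event == 1L & data$time <= tt])
    if (length(et) == 0) return(0)
    sum(vapply(et, function(s) {
      sum(data$time == s & data$event == 1L) / sum(w[data$time >= s])
    }, numeric(1)))
  }, numeric(1))
  data$event - ch0 * w
}

#' K-fold cross-validated training
#'
#' Seeded k-fold partition of the cohort; each fold trains on the
#' remaining folds and reports the held-out concordance of the risk
#' score.  `k_start`/`k_end` (1-based; -1 = no restriction) restrict
#' the folds actually run.
#'
#' @param cohort A cohort-like list (see [milcox()]).
#' @param config A [milcox_config].
#' @param gene_panel Optional screened gene panel.
#' @return List of per-fold results: `fold`, `fit`, `test_idx`,
#'   `c_index`.
#' @export
milcox_cv <- function(cohort, config = milcox_config(), gene_panel = NULL) {
  patients <- as_surv_data(cohort$patients)
  n <- nrow(patients)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  folds <- sample(rep(seq_len(config$k_folds), length.out = n))
  from <- if (config$k_start > 0) config$k_start else 1L
  to <- if (config$k_end > 0) config$k_end else config$k_folds
  res <- list()
  for (k in from:to) {
    test_idx <- which(folds == k)
    train_idx <- which(folds != k)
    sub <- subset_cohort(cohort, train_idx)
    fit <- milcox(sub, config, gene_panel)
    tst <- subset_cohort(cohort, test_idx)
    pr <- predict(fit, tst)
    ci <- tryCatch(concordance_index(pr$risk, tst$patients),
                   error = function(e) NA_real_)
    res[[length(res) + 1L]] <- list(fold = k, fit = fit,
                                    test_idx = test_idx, c_index = ci)
  }
  res
}

#' Subset a cohort by patient index
#'
#' @param cohort A cohort-like list.
#' @param idx Integer patient indices.
#' @return The subset cohort with all modalities aligned.
#' @export
subset_cohort <- function(cohort, idx) {
  patients <- as_surv_data(cohort$patients)[idx, , drop = FALSE]
  class(patients) <- c("surv_data", "data.frame")
  out <- list(patients = patients, bags = cohort$bags[idx])
  if (!is.null(cohort$expression)) {
    out$expression <- cohort$expression[, patients$patient_id, drop = FALSE]
  }
  if (!is.null(cohort$clinical)) {
    out$clinical <- cohort$clinical[patients$patient_id, , drop = FALSE]
  }
  if (!is.null(cohort$truth)) {
    out$truth <- lapply(cohort$truth, function(tr) {
      if (is.matrix(tr)) tr
      else if (length(tr) == length(cohort$bags)) tr[idx]
      else tr
    })
  }
  out
}
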