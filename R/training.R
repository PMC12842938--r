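# Losses, Gumbel-Softmax sampling, temperature annealing, and the Adam
# training loop with early stopping on validation loss.

#' Gumbel-Softmax sample
#'
#' Draws b_k ~ Gumbel(0, 1) and returns softmax((logits + b)/tau). With
#' \code{hard = TRUE} the one-hot of the soft sample's argmax is returned
#' (the straight-through forward); since argmax((logits + b)/tau) does not
#' depend on tau, hard selection frequencies follow
#' categorical(softmax(logits)) exactly (the Gumbel-max property).
#'
#' @param logits Numeric vector of unnormalised gate scores.
#' @param tau Temperature, > 0.
#' @param seed Optional integer seed for the Gumbel draws.
#' @param hard If TRUE return the one-hot of the argmax of the soft sample.
#' @return Numeric vector on the simplex (one-hot when \code{hard}).
#' @export
gumbel_softmax_sample <- function(logits, tau, seed = NULL, hard = FALSE) {
  if (tau <= 0) stop("tau must be > 0")
  if (!all(is.finite(logits))) stop("non-finite logits")
  g <- if (is.null(seed)) -log(-log(stats::runif(length(logits))))
       else with_seed(seed, -log(-log(stats::runif(length(logits)))))
  z <- (logits + g) / tau
  z <- z - max(z)
  soft <- exp(z) / sum(exp(z))
  if (!hard) return(soft)
  hardv <- numeric(length(logits))
  hardv[which.max(soft)] <- 1
  hardv
}

#' Geometric temperature annealing
#'
#' tau(e) = tau_start * (tau_end/tau_start)^(e/(epochs-1)) for 0-based epoch
#' e, so the schedule starts at tau_start and ends exactly at tau_end,
#' decreasing geometrically (high to low).
#'
#' @param epoch 0-based epoch index.
#' @param schedule List with \code{tau_start}, \code{tau_end}, \code{epochs}.
#' @return Temperature for the epoch.
#' @export
anneal_temperature <- function(epoch, schedule) {
  with(schedule, {
    if (epochs <= 1L) return(tau_end)
    tau_start * (tau_end / tau_start)^(epoch / (epochs - 1))
  })
}

#' Resource-aware loss breakdown
#'
#' total = task_loss + lambda * expected_cost(path probs, fusion probs).
#'
#' @param task_loss Scalar task loss.
#' @param path_probs Length-4 expert probabilities.
#' @param fusion_probs Per-unit operation probabilities (see
#'   [expected_cost()]); may be NULL.
#' @param cost Cost model from [cost_model()].
#' @param lambda Penalty weight, >= 0.
#' @return A \code{loss_breakdown} list: task_loss, cost_penalty, total,
#'   lambda.
#' @export
resource_aware_loss <- function(task_loss, path_probs, fusion_probs = NULL,
                                cost = cost_model(), lambda = 0.01) {
  if (lambda < 0) stop("lambda must be >= 0")
  penalty <- expected_cost(path_probs, fusion_probs, cost)
  structure(list(task_loss = task_loss, cost_penalty = penalty,
                 total = task_loss + lambda * penalty, lambda = lambda),
            class = "loss_breakdown")
}

#' Focal loss
#'
#' Mean over samples of -alpha_y (1 - p_y)^gamma log(p_y), the standard
#' focusing modification of cross-entropy that down-weights easy examples;
#' gamma = 0 with unit alpha recovers cross-entropy. Probabilities are
#' clamped at 1e-12 before the log.
#'
#' @param probs n x K matrix of class probabilities (rows on the simplex).
#' @param labels Length-n integer vector of 0-based class labels in 0..K-1.
#' @param gamma Focusing parameter, >= 0.
#' @param alpha Class weight: scalar or length-K vector (indexed by class).
#' @return Scalar loss.
#' @export
focal_loss <- function(probs, labels, gamma = 2, alpha = 1) {
  probs <- as.matrix(probs)
  if (gamma < 0) stop("gamma must be >= 0")
  n <- nrow(probs)
  if (length(labels) != n) stop("labels length must match probs rows")
  py <- pmax(probs[cbind(seq_len(n), labels + 1L)], 1e-12)
  a <- if (length(alpha) == 1L) rep(alpha, n) else alpha[labels + 1L]
  mean(-a * (1 - py)^gamma * log(py))
}

#' Classification head
#'
#' Time-mean pooling of the final fused state followed by a linear map to two
#' logits and a softmax.
#'
#' @param h_N Final fused token matrix (or node with \code{tape}).
#' @param params List with a linear layer \code{cls} (\code{W}, \code{b}).
#' @param tape Optional autodiff tape; with a tape the logit node is
#'   returned (probabilities via softmax of its value).
#' @return Length-2 probability vector (numeric path), or the 1 x 2 logit
#'   node (tape path).
#' @export
classify_head <- function(h_N, params, tape = NULL) {
  if (is_ad_node(h_N))
    return(ad_linear(tape, ad_rowmean(tape, h_N), params$cls))
  z <- as.numeric(global_context(h_N, params$cls))
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

#' Assemble a full model
#'
#' Initialises all parameters (MTEM pipelines for both modalities, the
#' dynamic fusion stage, the classifier head) from the config's seed, sized
#' for the given data dimensions.
#'
#' @param cfg A [run_config()].
#' @param T_a,T_v Sequence lengths the model will see (sizes the positional
#'   tables).
#' @return A \code{dynfuse_model} list with \code{params}, \code{cfg} and the
#'   flat parameter list used by the optimiser.
#' @export
build_model <- function(cfg, T_a, T_v) {
  n_short <- function(T) (T - cfg$patch_short_len) %/% cfg$patch_short_stride + 1L
  params <- with_seed(cfg$seed, list(
    mtem_a = mtem_params(cfg, max_short_tokens = n_short(T_a)),
    mtem_v = mtem_params(cfg, max_short_tokens = n_short(T_v)),
    dynmm = dynmm_params(cfg, compress_seed = cfg$seed + 7L),
    cls = new_linear(cfg$d_model, 2L)
  ))
  flat <- collect_params(params)
  structure(list(params = params, cfg = cfg, flat = flat),
            class = "dynfuse_model")
}

#' Full forward pass for one sample
#'
#' MTEM on each modality, dynamic fusion, classifier head.
#'
#' @param model A [build_model()] result (or checkpointed model).
#' @param sample A [multimodal_sample()].
#' @param mode "hard" (inference) or "soft" (training decisions).
#' @param tau Gumbel-Softmax temperature for soft mode.
#' @param training Logical; enables dropout.
#' @param tape Optional autodiff tape.
#' @param record Optional attention-recording environment.
#' @param force_path,force_ops Optional forced decisions (see
#'   [dynmm_forward()]).
#' @return List with class probabilities, logits (node under a tape), the
#'   path and fusion decisions, MTEM router weights, and the probability
#'   nodes used by the loss.
#' @export
model_forward <- function(model, sample, mode = "hard", tau = 1,
                          training = FALSE, tape = NULL, record = NULL,
                          force_path = NULL, force_ops = NULL) {
  own_tape <- is.null(tape)
  tp <- if (own_tape) ad_tape() else tape
  cfg <- model$cfg
  ma <- mtem_forward(sample$audio, model$params$mtem_a, cfg, tape = tp,
                     record = record, label = "mtem-audio")
  mv <- mtem_forward(sample$video, model$params$mtem_v, cfg, tape = tp,
                     record = record, label = "mtem-video")
  dyn <- dynmm_forward(ma$tokens, mv$tokens, model$params$dynmm, cfg,
                       mode = mode, tau = tau, training = training,
                       force_path = force_path, force_ops = force_ops,
                       tape = tp, record = record)
  logits <- classify_head(dyn$h, model$params, tape = tp)
  z <- as.numeric(logits$val)
  z <- z - max(z)
  probs <- exp(z) / sum(exp(z))
  list(probs = probs, logits = logits, path = dyn$path, fusion = dyn$fusion,
       router_a = ma$router, router_v = mv$router,
       path_probs_node = dyn$path_probs_node,
       fusion_probs_node = dyn$fusion_probs_node,
       h = if (own_tape) dyn$h$val else dyn$h)
}

# scalar expected-cost node from probability nodes (soft decisions)
expected_cost_node <- function(tape, path_probs_node, fusion_probs_node, cost) {
  ec <- ad_matmul(tape, path_probs_node,
                  ad_const(tape, matrix(cost$expert_cost, 4L, 1L)))
  for (pj in fusion_probs_node) {
    ec <- ad_add(tape, ec,
                 ad_matmul(tape, pj, ad_const(tape, matrix(cost$op_cost, 4L, 1L))))
  }
  ec
}

# focal loss node for one sample from a 1x2 logit node
focal_loss_node <- function(tape, logits, label, gamma, alpha) {
  p <- ad_softmax_rows(tape, logits)
  py <- ad_pick(tape, p, 1L, label + 1L)
  one_minus <- ad_scale(tape, ad_sub(tape, ad_const(tape, matrix(1, 1L, 1L)), py), 1)
  term <- ad_mul(tape, ad_pow(tape, one_minus, gamma),
                 ad_log(tape, py))
  ad_scale(tape, term, -alpha[label + 1L])
}

#' Train a model on a dataset
#'
#' Splits the samples by id (largest-remainder apportionment of the config's
#' ratios), then optimises all parameters with Adam. Training uses soft
#' (Gumbel-Softmax) decisions at the annealed temperature with
#' straight-through execution; validation uses hard decisions so early
#' stopping tracks deployable behaviour. The loss is cross-entropy (or focal
#' with inverse-class-frequency weights) plus lambda times the expected
#' decision cost. All randomness derives from the config seed; two runs with
#' the same data and config are identical.
#'
#' @param samples List of [multimodal_sample()] (or a container path).
#' @param cfg A [run_config()].
#' @param split Optional precomputed [make_split()]; defaults to a fresh
#'   split from the config.
#' @param verbose Print per-epoch progress.
#' @return A \code{dynfuse_fit}: the model (best-validation weights),
#'   \code{history} data frame (per-epoch loss breakdown, temperature,
#'   validation loss/accuracy), the split, and the best epoch.
#' @export
train_model <- function(samples, cfg, split = NULL, verbose = FALSE) {
  if (is.character(samples)) samples <- read_feature_container(samples)
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  names(samples) <- ids
  if (is.null(split)) split <- make_split(ids, cfg$split_ratios, cfg$seed)
  if (length(split$train) == 0L || length(split$val) == 0L)
    stop("train and validation splits must be non-empty")
  model <- build_model(cfg, T_a = nrow(samples[[1]]$audio),
                       T_v = nrow(samples[[1]]$video))
  flat <- model$flat
  opt <- adam_state(flat)
  cost <- cost_model()
  sched <- list(tau_start = cfg$tau_start, tau_end = cfg$tau_end,
                epochs = cfg$max_epochs)
  train_labels <- vapply(samples[split$train], function(s) s$label, integer(1))
  alpha <- if (cfg$loss == "focal") {
    freq <- c(mean(train_labels == 0L), mean(train_labels == 1L))
    freq[freq == 0] <- 1
    w <- 1 / freq
    w / sum(w) * 2
  } else c(1, 1)

  history <- list()
  best_val <- Inf; best_snap <- snapshot_params(flat); best_epoch <- 0L
  wait <- 0L

  eval_split <- function(idset) {
    tot <- 0; correct <- 0L
    for (id in idset) {
      s <- samples[[id]]
      fw <- model_forward(model, s, mode = "hard", training = FALSE)
      py <- max(fw$probs[s$label + 1L], 1e-12)
      task <- if (cfg$loss == "focal")
        -alpha[s$label + 1L] * (1 - py)^cfg$focal_gamma * log(py)
      else -log(py)
      ecost <- expected_cost(fw$path$hard, fw$fusion$hard, cost)
      tot <- tot + task + cfg$lambda * ecost
      if (which.max(fw$probs) == s$label + 1L) correct <- correct + 1L
    }
    list(loss = tot / length(idset), acc = correct / length(idset))
  }

  for (epoch in seq_len(cfg$max_epochs) - 1L) {
    tau <- anneal_temperature(epoch, sched)
    set.seed(cfg$seed + 1000L * (epoch + 1L))
    order_ids <- sample(split$train)
    ep_task <- 0; ep_cost <- 0
    batches <- split(order_ids, ceiling(seq_along(order_ids) / cfg$batch_size))
    for (batch in batches) {
      zero_grads(flat)
      for (id in batch) {
        s <- samples[[id]]
        tp <- ad_tape()
        fw <- model_forward(model, s, mode = "soft", tau = tau,
                            training = TRUE, tape = tp)
        task_node <- if (cfg$loss == "focal")
          focal_loss_node(tp, fw$logits, s$label, cfg$focal_gamma, alpha)
        else ad_ce_loss(tp, fw$logits, s$label + 1L)
        ec <- expected_cost_node(tp, fw$path_probs_node, fw$fusion_probs_node,
                                 cost)
        total <- ad_add(tp, task_node, ad_scale(tp, ec, cfg$lambda))
        ad_backward(tp, total)
        ep_task <- ep_task + as.numeric(task_node$val)
        ep_cost <- ep_cost + as.numeric(ec$val)
      }
      scale_grads(flat, 1 / length(batch))
      opt <- adam_step(flat, opt, cfg$lr)
    }
    n_tr <- length(split$train)
    val <- eval_split(split$val)
    history[[length(history) + 1L]] <- data.frame(
      epoch = epoch, task_loss = ep_task / n_tr, cost_penalty = ep_cost / n_tr,
      total = ep_task / n_tr + cfg$lambda * ep_cost / n_tr, tau = tau,
      val_loss = val$loss, val_acc = val$acc)
    if (verbose)
      message(sprintf("epoch %3d  task %.4f  cost %.3f  tau %.3f  val %.4f acc %.3f",
                      epoch, ep_task / n_tr, ep_cost / n_tr, tau, val$loss,
                      val$acc))
    if (val$loss < best_val - 1e-9) {
      best_val <- val$loss
      best_snap <- snapshot_params(flat)
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > cfg$patience) break
    }
  }
  restore_params(flat, best_snap)
  structure(list(model = model, history = do.call(rbind, history),
                 split = split, best_epoch = best_epoch,
                 best_val_loss = best_val, alpha = alpha),
            class = "dynfuse_fit")
}

#' Predict on samples with hard decisions
#'
#' @param fit A \code{dynfuse_fit} from [train_model()], or a
#'   \code{dynfuse_model}.
#' @param samples List of [multimodal_sample()].
#' @return Data frame with sample_id, label, positive-class probability,
#'   predicted class, selected path, and per-sample expected (nominal) cost
#'   of the executed decisions.
#' @export
predict_model <- function(fit, samples) {
  model <- if (inherits(fit, "dynfuse_fit")) fit$model else fit
  cost <- cost_model()
  rows <- lapply(samples, function(s) {
    fw <- model_forward(model, s, mode = "hard", training = FALSE)
    data.frame(sample_id = s$sample_id, label = s$label,
               prob_pos = fw$probs[2], pred = which.max(fw$probs) - 1L,
               path = fw$path$selected,
               cost = expected_cost(fw$path$hard, fw$fusion$hard, cost))
  })
  do.call(rbind, rows)
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint stores the config, all parameter values and the training
#' history; [load_checkpoint()] rebuilds the model and restores the weights.
#'
#' @param fit A \code{dynfuse_fit}.
#' @param path Destination file.
#' @return \code{save_checkpoint}: the path, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "dynfuse_fit"))
  saveRDS(list(kind = "dynfuse-checkpoint", cfg = fit$model$cfg,
               values = snapshot_params(fit$model$flat),
               dims = list(
                 pos_a = nrow(fit$model$params$mtem_a$pos$val),
                 pos_v = nrow(fit$model$params$mtem_v$pos$val)),
               history = fit$history, split = fit$split,
               best_epoch = fit$best_epoch), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return \code{load_checkpoint}: a \code{dynfuse_fit} with restored
#'   weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$kind, "dynfuse-checkpoint")) stop("not a checkpoint: ", path)
  cfg <- ck$cfg
  # rebuild with positional capacity matching the stored tables
  T_a <- (ck$dims$pos_a - 1L) * cfg$patch_short_stride + cfg$patch_short_len
  T_v <- (ck$dims$pos_v - 1L) * cfg$patch_short_stride + cfg$patch_short_len
  model <- build_model(cfg, T_a = T_a, T_v = T_v)
  restore_params(model$flat, ck$values)
  structure(list(model = model, history = ck$history, split = ck$split,
                 best_epoch = ck$best_epoch), class = "dynfuse_fit")
}
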