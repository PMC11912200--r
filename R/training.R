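# Maximum-likelihood training of the flow with periodic BAR_V evaluation.
# The loss is the negative batch mean of the generalized work
# phi = beta U + ln q; beta U does not depend on the model parameters, so
# the gradient equals that of -mean(ln q), but keeping the energies in the
# reported loss makes it read, up to the sign, as f - KL(p||q): at the
# optimum (q = p) the loss equals -f exactly.

#' Training configuration
#'
#' Defaults follow the study conditions: training batches of 1000 frames,
#' evaluation batches of 10000 validation frames, a frame-level 3:1
#' training:validation split applied once before any fitting, a stride of
#' 25 training batches between evaluations, and Adam with learning rate
#' 1e-3 (no schedule). Training runs until the running weighted average of
#' the BAR_V estimates plateaus (relative change below `plateau_tol` over
#' the last quarter of evaluations) or `max_steps` is reached.
#'
#' @param train_batch training batch size.
#' @param eval_batch validation/model-sample batch size per evaluation.
#' @param split_ratio training fraction (3:1 split = 0.75).
#' @param eval_stride training batches between evaluations.
#' @param lr Adam learning rate (default 2e-3, no schedule).
#' @param max_steps hard cap on training batches.
#' @param min_evals minimum evaluations before the plateau criterion may
#'   stop training.
#' @param plateau_tol relative-change threshold for the plateau criterion.
#' @param seed seed controlling the split, batching and evaluation draws.
#' @return object of class `training_config`.
#' @export
training_config <- function(train_batch = 1000L, eval_batch = 10000L,
                            split_ratio = 0.75, eval_stride = 25L,
                            lr = 2e-3, max_steps = 1000L, min_evals = 12L,
                            plateau_tol = 1e-3, seed = 1L) {
  structure(
    list(train_batch = as.integer(train_batch),
         eval_batch = as.integer(eval_batch),
         split_ratio = split_ratio, eval_stride = as.integer(eval_stride),
         lr = lr, max_steps = as.integer(max_steps),
         min_evals = as.integer(min_evals), plateau_tol = plateau_tol,
         seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Maximum-likelihood training loss
#'
#' Negative batch mean of the generalized work
#' \eqn{\phi(r) = \beta U(r) + \ln q(r)}. Shifting the energies by a
#' constant shifts the loss but not its gradient; at \eqn{q = p} the loss
#' equals \eqn{-f}. Batches containing non-finite \eqn{\ln q} are reported
#' via the returned `n_nonfinite`.
#'
#' @param model a flow model.
#' @param frames a batch of frames.
#' @param beta_u their reduced potential energies.
#' @return list with `loss` and `n_nonfinite`.
#' @export
ml_loss <- function(model, frames, beta_u) {
  lq <- flow_log_prob(model, frames)
  phi <- generalized_work(beta_u, lq)
  ok <- is.finite(phi)
  list(loss = -mean(phi[ok]), n_nonfinite = sum(!ok))
}

# one gradient step on pre-encoded marginals; returns updated params/state
.train_step <- function(model, x, opt) {
  B <- nrow(x)
  fw <- flow_forward(model, x, keep_cache = TRUE)
  bl <- base_logdens_z(model, fw$z, grad = TRUE)
  g <- -bl$grad / B
  g_ld <- rep(-1 / B, B)
  grads <- vector("list", length(model$layers))
  for (l in rev(seq_along(model$layers))) {
    bk <- coupling_backward(model$layers[[l]], fw$caches[[l]], g, g_ld)
    grads[[l]] <- list(W = bk$gW, b = bk$gb)
    g <- bk$g_x
  }
  st <- adam_step(flow_params(model), grads, opt$state, lr = opt$lr)
  list(model = flow_set_params(model, st$params),
       state = st$state,
       mean_logq_part = mean(bl$value + fw$logdet))
}

#' Train a flow model with periodic BAR_V evaluation
#'
#' Runs stochastic maximum-likelihood training; every `eval_stride` batches
#' it draws an evaluation batch of validation frames (with replacement if
#' the validation split is smaller, which is logged) and an equal number of
#' model samples, records the raw `f^BAR_V(i) +/- SE(i)` and `f^ML(i)`
#' (mean generalized work on the validation batch), and updates the
#' overfitting-aware weighted running average, which also provides the
#' plateau stopping criterion. All randomness is governed by the config
#' seed: identical (seed, config, data) reproduce the records exactly.
#'
#' The fixed representation layers of the model were fitted on the entire
#' data set when the model was built; the split here only controls which
#' frames feed gradient batches versus evaluations.
#'
#' @param model a [build_flow_model()] flow (fitted on this data set).
#' @param frames the full data set of frames.
#' @param beta_u reduced potential energies of `frames`.
#' @param potential function mapping generated frames to their reduced
#'   potential energies (used on model samples during evaluation).
#' @param config a [training_config()].
#' @param verbose print evaluation records as they are produced.
#' @return list with the trained `model`, `records` (class `fe_training`
#'   tibble: step, raw estimate, SE, f_ML, running weighted average), and
#'   `final` (one-row summary tibble).
#' @export
train_flow <- function(model, frames, beta_u, potential,
                       config = training_config(), verbose = FALSE) {
  enc <- model$encoder
  ed <- encode_frames(enc, frames)
  x_all <- ed$x
  lv_all <- ed$log_volume
  n <- nrow(x_all)
  set.seed(config$seed)
  n_train <- floor(config$split_ratio * n)
  idx_train <- sample.int(n, n_train)
  idx_val <- setdiff(seq_len(n), idx_train)
  if (config$eval_batch > length(idx_val)) {
    message(sprintf(
      "evaluation batch (%d) exceeds validation split (%d): sampling with replacement",
      config$eval_batch, length(idx_val)
    ))
  }
  opt <- list(state = adam_init(flow_params(model)), lr = config$lr)
  recs <- list()
  skipped <- 0L
  for (step in seq_len(config$max_steps)) {
    b <- idx_train[sample.int(n_train, config$train_batch,
                              replace = config$train_batch > n_train)]
    st <- tryCatch(.train_step(model, x_all[b, , drop = FALSE], opt),
                   error = function(e) NULL)
    if (is.null(st) || !is.finite(st$mean_logq_part)) {
      skipped <- skipped + 1L
      next
    }
    model <- st$model
    opt$state <- st$state
    if (step %% config$eval_stride == 0L) {
      vb <- idx_val[sample.int(length(idx_val), config$eval_batch,
                               replace = config$eval_batch > length(idx_val))]
      fv <- flow_forward(model, x_all[vb, , drop = FALSE])
      lq_val <- base_logdens_z(model, fv$z)$value + fv$logdet + lv_all[vb]
      phi_p <- generalized_work(beta_u[vb], lq_val)
      smp <- flow_sample(model, config$eval_batch)
      phi_q <- generalized_work(potential(smp$frames), smp$log_q)
      i_eval <- length(recs) + 1L
      est <- bar_v(work_set(phi_p, phi_q), eval_index = i_eval)
      recs[[i_eval]] <- tibble(
        step = step, eval_index = i_eval,
        f = est$f, se = est$se, f_ml = mean(phi_p[is.finite(phi_p)]),
        loss = -mean(phi_p[is.finite(phi_p)]), flagged = est$flagged
      )
      if (verbose) {
        message(sprintf("step %5d  f_BAR_V = %9.4f +/- %.4f  f_ML = %9.4f",
                        step, est$f, est$se, recs[[i_eval]]$f_ml))
      }
      tb <- dplyr::bind_rows(recs)
      # plateau stopping: needs min_evals evaluations, a currently
      # overlapping (unflagged) estimator, and a stable running average
      if (i_eval >= config$min_evals && sum(!tb$flagged) >= config$min_evals / 2 &&
            !tb$flagged[i_eval]) {
        wra <- suppressWarnings(
          weighted_running_average(tb$f, tb$se, f_ml = tb$f_ml)
        )
        tail_n <- max(2L, ceiling(i_eval * 0.25))
        fb <- tail(wra$f_bar, tail_n)
        if (max(abs(fb - fb[length(fb)])) <
              config$plateau_tol * max(abs(fb[length(fb)]), 1)) {
          break
        }
      }
    }
  }
  records <- dplyr::bind_rows(recs)
  wra <- weighted_running_average(records$f, records$se, f_ml = records$f_ml)
  records$f_bar <- wra$f_bar
  records$se_bar <- wra$se_bar
  records$weight <- wra$weight
  class(records) <- c("fe_training", class(records))
  final <- tibble(
    f = tail(records$f_bar, 1), se = tail(records$se_bar, 1),
    estimator = "BAR_V", n_evals = nrow(records),
    n_train = n_train, n_val = length(idx_val), skipped_batches = skipped
  )
  list(model = model, records = records, final = final)
}

#' @export
tidy.fe_training <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.fe_training <- function(x, ...) {
  tibble(
    f_bar = tail(x$f_bar, 1), se_bar = tail(x$se_bar, 1),
    n_evals = nrow(x), f_ml_max = max(x$f_ml)
  )
}

#' @export
autoplot.fe_training <- function(object, true_f = NULL, ...) {
  df <- as_tibble(unclass(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$eval_index)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$f - .data$se, ymax = .data$f + .data$se
    ), fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$f), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$f_bar), colour = "black") +
    ggplot2::labs(x = "evaluation", y = expression(f ~ "(" * k[B] * T * ")"),
                  title = "Raw BAR_V estimates and weighted running average") +
    ggplot2::theme_minimal()
  if (!is.null(true_f)) {
    p <- p + ggplot2::geom_hline(yintercept = true_f, linetype = 2)
  }
  p
}
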