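# Training: Adam optimization, three-phase curriculum over quality bins, and
# gradient-episodic-memory (GEM) projection against forgetting.

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param beta1,beta2,adam_eps Adam moment decay rates and epsilon.
#' @param lr_decay_step multiply the learning rate by `lr_decay_factor` every
#'   this many optimization steps (Inf disables the schedule).
#' @param lr_decay_factor learning-rate decay multiplier.
#' @param epochs_per_phase integer vector of length 3: epochs for curriculum
#'   phases 1 (bin 1), 2 (bins 1-2) and 3 (bins 1-3).
#' @param memory_size number of episodic-memory examples drawn from previous
#'   phases (default 5).
#' @param dice_weight fraction of the Dice term in the combined loss, in
#'   [0, 1].
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement) per phase; Inf disables early stopping.
#' @param restore_best when a validation set is supplied, return the weights
#'   from the epoch with the lowest validation loss instead of the final
#'   epoch's (default TRUE).
#' @param seed seed governing example order, dropout and memory sampling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, lr_decay_step = Inf,
                         lr_decay_factor = 0.1,
                         epochs_per_phase = c(6L, 4L, 3L),
                         memory_size = 5L, dice_weight = 0.5,
                         patience = Inf, restore_best = TRUE, seed = 1L) {
  if (length(epochs_per_phase) != 3L || any(epochs_per_phase < 0))
    stop("`epochs_per_phase` must be 3 non-negative integers")
  if (memory_size < 0) stop("`memory_size` must be >= 0")
  if (dice_weight < 0 || dice_weight > 1) stop("`dice_weight` must be in [0, 1]")
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, lr_decay_step = lr_decay_step,
                 lr_decay_factor = lr_decay_factor,
                 epochs_per_phase = as.integer(epochs_per_phase),
                 memory_size = as.integer(memory_size),
                 dice_weight = dice_weight, patience = patience,
                 restore_best = isTRUE(restore_best),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Curriculum phase definition
#'
#' Phase 1 trains on bin 1 only, phase 2 on bins 1-2, phase 3 on all three
#' bins (bins order decreasing map quality).
#'
#' @param phase_index 1, 2 or 3.
#' @return A list with `phase_index` and `bins_included`.
#' @export
curriculum_phase <- function(phase_index) {
  phase_index <- as.integer(phase_index)
  if (!phase_index %in% 1:3) stop("`phase_index` must be 1, 2 or 3")
  list(phase_index = phase_index, bins_included = seq_len(phase_index))
}

# ---- parameter flattening ----------------------------------------------------

flatten_params <- function(plist) unlist(plist, use.names = FALSE)

unflatten_params <- function(vec, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    v <- vec[(pos + 1L):(pos + n)]
    if (!is.null(dim(template[[nm]]))) dim(v) <- dim(template[[nm]])
    out[[nm]] <- v
    pos <- pos + n
  }
  out
}

# ---- GEM gradient projection -------------------------------------------------

#' Gradient-episodic-memory projection
#'
#' If the proposed gradient does not conflict with the memory gradient
#' (`sum(grad * mem_grad) >= 0`) it is returned unchanged; otherwise the
#' minimal-norm correction is applied that makes the dot product zero:
#' `grad - (grad . mem / ||mem||^2) * mem`. This keeps later-phase updates
#' from increasing the loss on examples remembered from earlier phases.
#'
#' @param grad numeric parameter-gradient vector.
#' @param mem_grad memory gradient vector of the same length; must not be
#'   all zero.
#' @return The (possibly projected) gradient vector.
#' @export
gem_project <- function(grad, mem_grad) {
  if (length(grad) != length(mem_grad))
    stop("`grad` and `mem_grad` must have identical length")
  m2 <- sum(mem_grad * mem_grad)
  if (m2 == 0) stop("`mem_grad` must not be all zero")
  dot <- sum(grad * mem_grad)
  if (dot >= 0) return(grad)
  grad - (dot / m2) * mem_grad
}

#' Sample the episodic memory set
#'
#' Uniform sample without replacement from the examples of previous phases;
#' if fewer examples exist than `memory_size`, all are returned. With no
#' previous examples the memory is empty and projection is disabled.
#'
#' @param previous_examples list (or vector) of available examples.
#' @param memory_size number to draw (default 5).
#' @param seed optional seed for reproducible sampling; when NULL the current
#'   RNG stream is used.
#' @return A subset of `previous_examples`.
#' @export
sample_episodic_memory <- function(previous_examples, memory_size = 5L,
                                   seed = NULL) {
  n <- length(previous_examples)
  if (n == 0L || memory_size == 0L) return(previous_examples[integer(0)])
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (n <= memory_size) return(previous_examples)
  previous_examples[sort(sample.int(n, memory_size))]
}

# ---- Adam --------------------------------------------------------------------

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad * grad
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# ---- training loop -----------------------------------------------------------

# prepare a case (density_map + label_grid) for the network: normalize, pad
prepare_case <- function(case, divisor = 4L) {
  pp <- pad_for_network(normalize_density(case$map), divisor)
  d <- dim(pp$map$data)
  x <- pp$map$data
  dim(x) <- c(d, 1L)
  y <- array(0L, dim = d)
  y[pp$pad$before[1] + seq_len(dim(case$labels$labels)[1]),
    pp$pad$before[2] + seq_len(dim(case$labels$labels)[2]),
    pp$pad$before[3] + seq_len(dim(case$labels$labels)[3])] <- case$labels$labels
  list(x = x, y = as.integer(y), pad = pp$pad)
}

# forward + backward on one prepared case; returns loss and flat gradient
case_gradient <- function(model, pc, weights, dice_weight) {
  fw <- unet_forward_core(model, pc$x, training = TRUE, keep = TRUE)
  ls <- loss_core(vol2mat(fw$probs), pc$y, weights, dice_weight, grad = TRUE)
  dlogits <- mat2vol(ls$dlogits, dim(pc$x)[1:3], 3L)
  grads <- unet_backward_core(model, dlogits, fw$cache)
  list(loss = ls$loss, gvec = flatten_params(grads[names(model$params)]))
}

#' Train the network with a three-phase curriculum and GEM
#'
#' Phase 1 trains on bin-1 examples only, phase 2 on bins 1-2, phase 3 on all
#' bins. At each phase transition an episodic memory of `memory_size`
#' examples is drawn from the bins of previous phases; during phases with a
#' non-empty memory, every optimization step computes the average gradient
#' over the memory examples and projects the current gradient with
#' [gem_project()] before the Adam update. Each batch is one component map
#' (component maps vary in size). The run is fully reproducible from
#' `config$seed`.
#'
#' @param model a `unet_model` (see [build_unet()]).
#' @param datasets_by_bin list of 3 lists of cases, each case a list with a
#'   `map` ([density_map()], 1 A per voxel) and `labels` ([label_grid()]).
#'   Bins 2 and 3 may be empty; bin 1 must not be.
#' @param config a [train_config()].
#' @param validation optional list of cases for per-epoch validation loss and
#'   early stopping.
#' @return A list: `model` (trained; with a validation set and
#'   `restore_best`, the weights of the best-validation epoch), `history`
#'   (per-epoch data.frame with phase, epoch, mean training loss, validation
#'   loss, learning rate), `gem_calls` (number of gradient projections
#'   evaluated) and `best_val_loss`.
#' @export
train_curriculum <- function(model, datasets_by_bin, config = train_config(),
                             validation = NULL) {
  stopifnot(inherits(model, "unet_model"), inherits(config, "train_config"))
  if (length(datasets_by_bin) != 3L)
    stop("`datasets_by_bin` must be a list of 3 bins")
  if (length(datasets_by_bin[[1]]) == 0L)
    stop("bin 1 is empty: phase 1 has no training examples")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  prepared <- lapply(datasets_by_bin, function(bin) lapply(bin, prepare_case))
  val_prep <- if (!is.null(validation)) lapply(validation, prepare_case)
  weights <- as.numeric(compute_class_weights(
    unlist(lapply(datasets_by_bin, function(bin) lapply(bin, `[[`, "labels")),
           recursive = FALSE)))

  theta <- flatten_params(model$params)
  state <- adam_state(length(theta))
  lr <- config$learning_rate
  step <- 0L
  gem_calls <- 0L
  hist <- list()
  best <- list(val = Inf, params = NULL)

  val_loss <- function() {
    if (is.null(val_prep)) return(NA_real_)
    mean(vapply(val_prep, function(pc) {
      fw <- unet_forward_core(model, pc$x, training = FALSE, keep = FALSE)
      loss_core(vol2mat(fw$probs), pc$y, weights, config$dice_weight)$loss
    }, numeric(1)))
  }

  for (phase in 1:3) {
    n_epochs <- config$epochs_per_phase[phase]
    pool <- do.call(c, prepared[seq_len(phase)])
    memory <- if (phase > 1L && config$memory_size > 0L) {
      prev <- do.call(c, prepared[seq_len(phase - 1L)])
      sample_episodic_memory(prev, config$memory_size)
    } else list()
    if (n_epochs == 0L) next

    best_val <- Inf
    stale <- 0L
    for (epoch in seq_len(n_epochs)) {
      order_idx <- sample.int(length(pool))
      losses <- numeric(length(pool))
      for (i in seq_along(order_idx)) {
        pc <- pool[[order_idx[i]]]
        cg <- case_gradient(model, pc, weights, config$dice_weight)
        gvec <- cg$gvec
        if (length(memory) > 0L) {
          mvec <- 0
          for (mc in memory) {
            mg <- case_gradient(model, mc, weights, config$dice_weight)
            mvec <- mvec + mg$gvec
          }
          mvec <- mvec / length(memory)
          if (sum(mvec * mvec) > 0) {
            gvec <- gem_project(gvec, mvec)
            gem_calls <- gem_calls + 1L
          }
        }
        up <- adam_step(theta, gvec, state, lr, config$beta1, config$beta2,
                        config$adam_eps)
        theta <- up$theta
        state <- up$state
        model$params <- unflatten_params(theta, model$params)
        step <- step + 1L
        if (is.finite(config$lr_decay_step) && step %% config$lr_decay_step == 0L)
          lr <- lr * config$lr_decay_factor
        losses[i] <- cg$loss
      }
      vl <- val_loss()
      hist[[length(hist) + 1L]] <- data.frame(
        phase = phase, epoch = epoch, train_loss = mean(losses),
        val_loss = vl, lr = lr)
      if (!is.na(vl) && config$restore_best && vl < best$val) {
        best$val <- vl
        best$params <- model$params
      }
      if (!is.na(vl) && is.finite(config$patience)) {
        if (vl < best_val - 1e-6) { best_val <- vl; stale <- 0L }
        else {
          stale <- stale + 1L
          if (stale >= config$patience) break
        }
      }
    }
  }
  if (!is.null(best$params)) model$params <- best$params
  list(model = model, history = do.call(rbind, hist), gem_calls = gem_calls,
       best_val_loss = if (is.finite(best$val)) best$val else NA_real_)
}
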