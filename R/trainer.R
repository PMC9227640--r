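# Alternating generator/discriminator optimization (one D step then one G
# step per mini-batch) with Adam, per the published recipe: lr 1e-4, betas
# (0.5, 0.999), batch 12, 1000 epochs, N(0, 0.02) init at paper scale; the
# desk profile scales this down for CPU runs. Loss variants mirror the
# objective ablation: "mse_jsd" (non-saturating adversarial + L2, default),
# "mse" (L2 only), "kl" (saturating adversarial + L2).

as_pair_arrays <- function(pair) {
  if (inherits(pair, "paired_sample"))
    list(pet = pair$pet$data, mri = pair$mri$data,
         subject_id = pair$subject_id)
  else list(pet = vol_data(pair$pet), mri = vol_data(pair$mri),
            subject_id = pair$subject_id %||% "subject")
}

#' Save / load a training checkpoint
#'
#' Single-file archive (RDS) holding generator and discriminator parameters,
#' both Adam states, the epoch counter, the RNG state, the configuration and
#' the training log — everything needed to resume bit-identically.
#'
#' @param state checkpoint list (as produced internally by [egan_train()]).
#' @param path file path.
#' @return `path` / the checkpoint list.
#' @export
save_checkpoint <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}

#' Train the translation GAN
#'
#' @param dataset list of [paired_sample()] objects (or lists with `pet` and
#'   `mri` arrays), all preprocessed to the configured cubic extent with
#'   values in \[-1, 1\].
#' @param cfg an [egan_config()].
#' @param w a [loss_weights()] object.
#' @param out_dir if non-`NULL`, checkpoints (`ckpt_epoch*.rds`, `last.rds`)
#'   and the log are written here every `cfg$checkpoint_every` epochs.
#' @param resume path to a checkpoint to continue from (restores parameters,
#'   optimizer state and RNG stream, then trains up to `cfg$epochs`).
#' @param ablate_sobel drop the geometric edge channel (ablation).
#' @param val_fraction fraction of `dataset` held out for validation L2
#'   tracking (0 disables; the best-validation checkpoint is kept when
#'   `out_dir` is set).
#' @param verbose print per-epoch losses.
#' @return List with `gen`, `disc`, `log` (one row per epoch: `loss_d`,
#'   `loss_g_adv`, `loss_g_l2`, `hybrid`, `sat_frac`, `val_l2`, `seconds`),
#'   `cfg`, `w`; when a validation split is active, also `best_gen`,
#'   `best_epoch` and `best_val` (the best-validation-L2 snapshot of the
#'   generator within this run).
#' @export
egan_train <- function(dataset, cfg = egan_config(), w = loss_weights(),
                       out_dir = NULL, resume = NULL, ablate_sobel = FALSE,
                       val_fraction = 0, verbose = FALSE) {
  stopifnot(length(dataset) >= 1)
  pairs <- lapply(dataset, as_pair_arrays)
  E <- cfg$extent
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (!identical(dim(p$pet), dim(p$mri)))
      stop("pair ", i, ": pet/mri shape mismatch")
    if (!all(dim(p$pet) == E))
      stop("pair ", i, ": expected ", E, "^3 volumes, got ",
           paste(dim(p$pet), collapse = "x"))
    rng <- range(p$pet, p$mri)
    if (rng[1] < -1 - cfg$range_tol || rng[2] > 1 + cfg$range_tol)
      stop("pair ", i, " has intensities outside [-1, 1]; preprocess first")
  }
  n_val <- if (val_fraction > 0) max(0L, round(length(pairs) * val_fraction)) else 0L
  if (n_val >= length(pairs)) stop("validation split leaves no training data")
  val_idx <- if (n_val > 0) tail(seq_along(pairs), n_val) else integer(0)
  tr_idx <- setdiff(seq_along(pairs), val_idx)

  adversarial <- cfg$loss_variant %in% c("mse_jsd", "kl")
  use_l2 <- cfg$loss_variant %in% c("mse_jsd", "mse")
  a1 <- w$alpha1; a2 <- w$alpha2

  edges <- lapply(pairs, function(p)
    if (ablate_sobel) NULL else apply_sobel(p$pet)$data)
  # the (pet, real-mri) discriminator input never changes; stack it once
  real_in <- lapply(pairs, function(p)
    array(c(p$pet, p$mri), c(E, E, E, 2L)))

  if (!is.null(resume)) {
    ck <- load_checkpoint(resume)
    gen <- ck$gen; disc <- ck$disc
    adamG <- ck$adamG; adamD <- ck$adamD
    start_epoch <- ck$epoch + 1L
    log <- ck$log
    assign(".Random.seed", ck$rng, envir = globalenv())
    best_val <- ck$best_val %||% Inf
  } else {
    set.seed(cfg$seed)
    gen <- generator_init(cfg)
    disc <- discriminator_init(cfg)
    adamG <- adam_init(gen$params)
    adamD <- adam_init(disc$params)
    start_epoch <- 1L
    log <- NULL
    best_val <- Inf
  }
  best_gen <- NULL
  best_epoch <- NA_integer_
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  eps_clamp <- 1e-7
  B_cfg <- cfg$batch_size
  # one-sided label smoothing: BCE target for real pairs (1 = none)
  tr_real <- cfg$real_label %||% 1
  # per-epoch learning-rate factor (cosine decays to 10% of the base rate)
  lr_factor <- function(epoch) {
    if (identical(cfg$lr_schedule, "cosine"))
      0.1 + 0.45 * (1 + cos(pi * (epoch - 1) / max(1, cfg$epochs - 1)))
    else 1
  }
  for (epoch in seq.int(start_epoch, length.out = max(0L, cfg$epochs - start_epoch + 1L))) {
    t0 <- proc.time()[["elapsed"]]
    lr_g <- cfg$lr * lr_factor(epoch)
    lr_d <- (cfg$lr_disc %||% cfg$lr) * lr_factor(epoch)
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / B_cfg))
    ep <- c(loss_d = 0, loss_g_adv = 0, loss_g_l2 = 0, hybrid = 0)
    sat_n <- 0L; sat_tot <- 0L
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      B <- length(idx)
      pets <- lapply(pairs[idx], `[[`, "pet")
      mris <- lapply(pairs[idx], `[[`, "mri")
      eds <- edges[idx]
      gf <- generator_forward_batch(pets, eds, gen, cfg, train = TRUE,
                                    ablate_sobel = ablate_sobel)
      gen$bn <- gf$bn
      fakes <- gf$out

      # One discriminator step and one generator step per batch. Both
      # gradients are evaluated at the current (pre-update) parameters; the
      # fake branch is forwarded once and its backward pass reused for the
      # discriminator's fake term and the generator's adversarial gradient
      # (the backward is linear in the upstream scalar dL/dprob).
      loss_d <- 0; loss_g_adv <- 0
      gouts <- vector("list", B)
      loss_l2 <- 0
      if (adversarial) {
        dgrads <- tree_zero_like(disc$params)
        dr <- numeric(B); df <- numeric(B)
      }
      for (b in seq_len(B)) {
        gout <- array(0, dim(fakes[[b]]))
        if (use_l2) {
          diff <- fakes[[b]] - mris[[b]]
          loss_l2 <- loss_l2 + mean(diff^2) / B
          gout <- gout + a2 * 2 * diff / (length(diff) * B)
        }
        if (adversarial) {
          fr <- disc_forward_one(pets[[b]], mris[[b]], disc$params, cfg,
                                 cache = TRUE, stacked = real_in[[idx[b]]])
          ff <- disc_forward_one(pets[[b]], fakes[[b]], disc$params, cfg,
                                 cache = TRUE)
          dr[b] <- fr$prob; df[b] <- ff$prob
          drc <- min(max(fr$prob, eps_clamp), 1 - eps_clamp)
          dfc <- min(max(ff$prob, eps_clamp), 1 - eps_clamp)
          br <- disc_backward_one(
            -(tr_real / drc - (1 - tr_real) / (1 - drc)) / B,
            disc$params, fr$cache, cfg)
          bu <- disc_backward_one(1, disc$params, ff$cache, cfg,
                                  need_gx = TRUE)
          dgrads <- tree_add(dgrads,
                             tree_add(br$grads,
                                      tree_scale(bu$grads, 1 / (B * (1 - dfc)))))
          if (cfg$loss_variant == "kl") {
            # saturating form: minimize log(1 - D)
            loss_g_adv <- loss_g_adv + log(1 - dfc) / B
            dprob <- -1 / (B * (1 - dfc))
          } else {
            # non-saturating form: minimize -log D
            loss_g_adv <- loss_g_adv - log(dfc) / B
            dprob <- -1 / (B * dfc)
          }
          gout <- gout + a1 * dprob * array(bu$gx[, , , 2L], dim(gout))
        }
        gouts[[b]] <- gout
      }
      if (adversarial) {
        al <- adversarial_losses(dr, df, eps_clamp)
        loss_d <- al$loss_d
        sat_n <- sat_n + sum(df < 1e-3); sat_tot <- sat_tot + B
        upd <- adam_step(disc$params, dgrads, adamD, lr_d, cfg$betas)
        disc$params <- upd$params; adamD <- upd$state
      }
      ggrads <- generator_backward_batch(gouts, gen, gf$cache, cfg,
                                         ablate_sobel = ablate_sobel)
      upd <- adam_step(gen$params, ggrads, adamG, lr_g, cfg$betas)
      gen$params <- upd$params; adamG <- upd$state

      hyb <- a1 * loss_g_adv + a2 * loss_l2
      if (!all(is.finite(c(loss_d, loss_g_adv, loss_l2, hyb))))
        stop(sprintf("non-finite loss at epoch %d, batch %d (loss_d=%g, loss_g_adv=%g, loss_g_l2=%g)",
                     epoch, bi, loss_d, loss_g_adv, loss_l2))
      nb <- length(batches)
      ep <- ep + c(loss_d, loss_g_adv, loss_l2, hyb) / nb
    }

    val_l2 <- NA_real_
    if (n_val > 0) {
      vl <- 0
      for (i in val_idx) {
        out <- generator_forward_batch(list(pairs[[i]]$pet), edges[i], gen,
                                       cfg, train = FALSE,
                                       ablate_sobel = ablate_sobel)$out[[1]]
        vl <- vl + mean((out - pairs[[i]]$mri)^2) / n_val
      }
      val_l2 <- vl
      if (val_l2 < best_val) {
        best_val <- val_l2
        best_gen <- gen
        best_epoch <- epoch
      }
    }
    row <- data.frame(epoch = epoch, loss_d = ep[["loss_d"]],
                      loss_g_adv = ep[["loss_g_adv"]],
                      loss_g_l2 = ep[["loss_g_l2"]],
                      hybrid = ep[["hybrid"]],
                      sat_frac = if (sat_tot > 0) sat_n / sat_tot else 0,
                      val_l2 = val_l2,
                      seconds = proc.time()[["elapsed"]] - t0)
    log <- rbind(log, row)
    if (verbose)
      message(sprintf("epoch %d: D %.4f | G adv %.4f | G l2 %.4f | hybrid %.4f",
                      epoch, row$loss_d, row$loss_g_adv, row$loss_g_l2,
                      row$hybrid))
    if (!is.null(out_dir)) {
      state <- list(gen = gen, disc = disc, adamG = adamG, adamD = adamD,
                    epoch = epoch, rng = get(".Random.seed", globalenv()),
                    cfg = cfg, w = w, log = log,
                    ablate_sobel = ablate_sobel, best_val = best_val)
      if (epoch %% cfg$checkpoint_every == 0L)
        save_checkpoint(state, file.path(out_dir, sprintf("ckpt_epoch%04d.rds", epoch)))
      save_checkpoint(state, file.path(out_dir, "last.rds"))
      if (!is.na(best_epoch) && best_epoch == epoch) {
        state$best_val <- best_val
        save_checkpoint(state, file.path(out_dir, "best.rds"))
      }
      write.table(log, file.path(out_dir, "train_log.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    }
  }
  list(gen = gen, disc = disc, log = log, cfg = cfg, w = w,
       ablate_sobel = ablate_sobel,
       best_gen = best_gen, best_epoch = best_epoch,
       best_val = if (is.finite(best_val)) best_val else NA_real_)
}
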