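# End-to-end pipeline over a phantom dataset directory: simulate ->
# preprocess -> train -> translate -> evaluate -> gamma -> report.
# One hierarchical config drives every stage; all defaults mirror the
# published recipe where one exists.

#' Default pipeline configuration
#'
#' A nested list understood by [run_pipeline()] and the command-line
#' front end. Unknown keys are rejected (fail fast). Training defaults
#' follow the published recipe (Adam 1e-4/(0.5, 0.999), batch 1, weight
#' decay 1e-4, loss weights 1/10/20); the `train` block here also
#' carries the desk-scale overrides used for phantom-sized runs.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    out_dir = "runs/phantom",
    seed = 1L,
    dataset = list(n_train = 8L, n_test = 2L),
    phantom = list(shape = c(16L, 64L, 64L), spacing = c(4, 4, 4)),
    artifact = list(shading_amp = 60, shading_scale = 80, streak_amp = 40,
                    streak_freq = 12, streak_count = 4L, lung_offset = 150,
                    noise_sd = 20),
    deform = list(magnitude = 2.5, smoothness = 6),
    preprocess = list(rigid = TRUE, deformable = TRUE),
    train = list(lr = 2e-3, epochs = 5L, ngf = 24L, ndf = 16L, nrf = 16L,
                 n_residual = 9L, g_norm = "instance",
                 regnet_warmup = 256L, gen_pretrain = 0L,
                 pretrain_lr = 1e-3, ema_decay = 0.99, lambda_adv = 1,
                 lambda_smooth = 10, lambda_corr = 20, batch_size = 1L,
                 weight_decay = 1e-4),
    dose = list(prescription_gy = 50.4, n_beams = 5L),
    gamma = list(criteria = list(c(3, 3), c(2, 2), c(1, 1)), cutoff = 10,
                 refine_per_dta = 3))
}

merge_config <- function(base, user, path = "") {
  if (is.null(user)) return(base)
  for (nm in names(user)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop(sprintf("unknown config key '%s'; valid keys here: %s", key,
                   paste(names(base), collapse = ", ")))
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], key)
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load a pipeline configuration
#'
#' Reads a YAML file (if given) and merges it over [default_config()];
#' unknown keys are an error naming the offending key.
#'
#' @param path YAML file path or `NULL` for pure defaults.
#' @param overrides named list merged last (e.g. from the command line).
#' @return validated config list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

patient_dirs <- function(cfg, split = NULL) {
  man <- read_manifest(file.path(cfg$out_dir, "manifest.txt"))
  pts <- man$patients
  if (!is.null(split)) pts <- pts[pts$split == split, ]
  file.path(cfg$out_dir, pts$patient)
}

read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found (run 'simulate' first): ",
                               path)
  ln <- readLines(path)
  kv <- strsplit(ln, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  pt <- grepl("^patient_", keys)
  patients <- data.frame(
    patient = sub("^patient_", "", keys[pt]),
    split = sub("^split=(\\S+).*", "\\1", vals[pt]),
    seed = as.integer(sub(".*seed=(\\d+).*", "\\1", vals[pt])))
  list(n_train = as.integer(vals[keys == "n_train"]),
       n_test = as.integer(vals[keys == "n_test"]),
       seed = as.integer(vals[keys == "seed"]), patients = patients)
}

pipeline_simulate <- function(cfg) {
  ph <- do.call(phantom_spec, cfg$phantom)
  ar <- do.call(artifact_spec, cfg$artifact)
  de <- do.call(deform_spec, cfg$deform)
  make_dataset(cfg$dataset$n_train, cfg$dataset$n_test, cfg$out_dir,
               seed = cfg$seed, phantom = ph, artifact = ar, deform = de,
               prescription_gy = cfg$dose$prescription_gy,
               n_beams = cfg$dose$n_beams)
}

pipeline_preprocess <- function(cfg) {
  for (pdir in patient_dirs(cfg)) {
    planning <- read_volume(file.path(pdir, "planning.nii.gz"), "planning")
    cbct <- read_volume(file.path(pdir, "cbct.nii.gz"), "cbct")
    if (isTRUE(cfg$preprocess$rigid)) {
      rr <- rigid_register(planning, cbct)
      aligned <- rr$resampled
      write_rigid_sidecar(rr$params, file.path(pdir, "rigid.txt"))
    } else aligned <- planning
    write_volume(aligned, file.path(pdir, "planning_aligned.nii.gz"))
  }
  if (isTRUE(cfg$preprocess$deformable)) {
    for (pdir in patient_dirs(cfg, "test")) {
      aligned <- read_volume(file.path(pdir, "planning_aligned.nii.gz"),
                             "planning")
      cbct <- read_volume(file.path(pdir, "cbct.nii.gz"), "cbct")
      dr <- deformable_register(aligned, cbct)
      write_volume(dr$dct, file.path(pdir, "dct.nii.gz"))
      write_field(dr$field, aligned$spacing,
                  file.path(pdir, "dct_field.nii.gz"))
    }
  }
  invisible(NULL)
}

pipeline_train <- function(cfg) {
  ds <- list()
  for (pdir in patient_dirs(cfg, "train")) {
    cbct <- read_volume(file.path(pdir, "cbct.nii.gz"), "cbct")
    f <- file.path(pdir, "planning_aligned.nii.gz")
    if (!file.exists(f)) f <- file.path(pdir, "planning.nii.gz")
    planning <- read_volume(f, "planning")
    ds <- c(ds, slice_dataset(cbct, planning))
  }
  tc <- train_config(lr = cfg$train$lr, epochs = cfg$train$epochs,
                     ngf = cfg$train$ngf, ndf = cfg$train$ndf,
                     nrf = cfg$train$nrf, n_residual = cfg$train$n_residual,
                     g_norm = cfg$train$g_norm,
                     regnet_warmup = cfg$train$regnet_warmup,
                     gen_pretrain = cfg$train$gen_pretrain,
                     pretrain_lr = cfg$train$pretrain_lr,
                     ema_decay = cfg$train$ema_decay,
                     lambda_adv = cfg$train$lambda_adv,
                     lambda_smooth = cfg$train$lambda_smooth,
                     lambda_corr = cfg$train$lambda_corr,
                     batch_size = cfg$train$batch_size,
                     weight_decay = cfg$train$weight_decay,
                     seed = cfg$seed)
  res <- train(ds, tc, checkpoint_path = file.path(cfg$out_dir,
                                                   "checkpoint.rds"))
  write_loss_curves(res$history, file.path(cfg$out_dir, "loss_curves.csv"))
  invisible(res)
}

pipeline_translate <- function(cfg) {
  ck <- load_checkpoint(file.path(cfg$out_dir, "checkpoint.rds"))
  for (pdir in patient_dirs(cfg, "test")) {
    cbct <- read_volume(file.path(pdir, "cbct.nii.gz"), "cbct")
    sct <- translate_volume(ck, cbct)
    write_volume(sct, file.path(pdir, "sct.nii.gz"))
  }
  invisible(NULL)
}

pipeline_evaluate <- function(cfg) {
  rows <- list()
  stats <- list()
  for (pdir in patient_dirs(cfg, "test")) {
    pt <- basename(pdir)
    day <- read_volume(file.path(pdir, "day.nii.gz"), "day")
    cbct <- read_volume(file.path(pdir, "cbct.nii.gz"), "cbct")
    sct <- read_volume(file.path(pdir, "sct.nii.gz"), "sct")
    f_dct <- file.path(pdir, "dct.nii.gz")
    refs <- list(day = day)
    if (file.exists(f_dct)) refs$dct <- read_volume(f_dct, "dct")
    # CBCT is compared after the same clip window as the translation
    cbct_c <- image_volume(pmin(pmax(cbct$data, -1000), 2000), cbct$spacing,
                           cbct$origin, "cbct")
    for (rn in names(refs)) {
      bm <- body_mask(refs[[rn]])
      for (ti in c("cbct", "sct")) {
        test <- if (ti == "cbct") cbct_c else sct
        sim <- image_similarity(test, refs[[rn]], bm)
        rows[[length(rows) + 1]] <- data.frame(
          patient = pt, image = ti, reference = rn, mae = sim$mae,
          rmse = sim$rmse, psnr = sim$psnr, n_voxels = sim$n)
      }
    }
    rois <- decode_rois(read_volume(file.path(pdir, "rois.nii.gz"))$data)
    images <- c(refs["day"], if (!is.null(refs$dct)) refs["dct"],
                list(cbct = cbct_c, sct = sct))
    stats[[length(stats) + 1]] <- eval_table(pt, images, rois)
  }
  sim_tab <- do.call(rbind, rows)
  utils::write.csv(sim_tab, file.path(cfg$out_dir, "similarity.csv"),
                   row.names = FALSE)
  write_eval_csv(do.call(rbind, stats),
                 file.path(cfg$out_dir, "roi_stats.csv"))
  invisible(sim_tab)
}

pipeline_gamma <- function(cfg) {
  rows <- list()
  dvh_rows <- list()
  for (pdir in patient_dirs(cfg, "test")) {
    pt <- basename(pdir)
    rois <- decode_rois(read_volume(file.path(pdir, "rois.nii.gz"))$data)
    imgs <- list(
      dct = read_volume(file.path(pdir, "dct.nii.gz"), "dct"),
      cbct = read_volume(file.path(pdir, "cbct.nii.gz"), "cbct"),
      sct = read_volume(file.path(pdir, "sct.nii.gz"), "sct"))
    # fix the plan scaling on the reference (dCT) grid so attenuation
    # differences between images appear as absolute dose differences
    ref_dose <- make_dose(rois, cfg$dose$prescription_gy, cfg$dose$n_beams,
                          density = imgs$dct)
    sc <- attr(ref_dose, "dose_scale")
    doses <- list(dct = ref_dose)
    for (ti in c("cbct", "sct"))
      doses[[ti]] <- make_dose(rois, cfg$dose$prescription_gy,
                               cfg$dose$n_beams, density = imgs[[ti]],
                               scale = sc)
    for (ti in c("cbct", "sct")) {
      for (cr in cfg$gamma$criteria) {
        gc <- gamma_criteria(cr[1], cr[2], cfg$gamma$cutoff)
        gm <- gamma_map(doses$dct, doses[[ti]], gc,
                        refine_per_dta = cfg$gamma$refine_per_dta)
        rows[[length(rows) + 1]] <- data.frame(
          patient = pt, image = ti, dta_mm = cr[2], dose_pct = cr[1],
          pass_rate = gm$pass_rate, n_evaluated = gm$n_evaluated)
      }
    }
    for (ti in names(doses)) {
      dp <- dvh_params(doses[[ti]], rois)
      dp$patient <- pt
      dp$image <- ti
      dvh_rows[[length(dvh_rows) + 1]] <- dp
    }
  }
  gtab <- do.call(rbind, rows)
  utils::write.csv(gtab, file.path(cfg$out_dir, "gamma.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, dvh_rows),
                   file.path(cfg$out_dir, "dvh_params.csv"),
                   row.names = FALSE)
  invisible(gtab)
}

pipeline_report <- function(cfg) {
  out <- cfg$out_dir
  sim <- utils::read.csv(file.path(out, "similarity.csv"))
  gam <- utils::read.csv(file.path(out, "gamma.csv"))
  med <- function(img, ref) stats::median(sim$mae[sim$image == img &
                                                    sim$reference == ref])
  lines <- c(
    "regganct phantom run report",
    sprintf("median MAE vs day CT:  CBCT %.1f HU   sCT %.1f HU",
            med("cbct", "day"), med("sct", "day")),
    if ("dct" %in% sim$reference)
      sprintf("median MAE vs dCT:     CBCT %.1f HU   sCT %.1f HU",
              med("cbct", "dct"), med("sct", "dct")),
    "mean gamma pass rates (%):")
  for (ti in c("cbct", "sct"))
    for (cr in cfg$gamma$criteria)
      lines <- c(lines, sprintf("  %-4s %g mm / %g %%: %.1f", ti, cr[2],
                                cr[1],
                                mean(gam$pass_rate[gam$image == ti &
                                                     gam$dta_mm == cr[2] &
                                                     gam$dose_pct == cr[1]])))
  writeLines(lines, file.path(out, "report.txt"))
  message(paste(lines, collapse = "\n"))
  invisible(lines)
}

write_run_manifest <- function(cfg) {
  out <- cfg$out_dir
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("run_manifest", files)]
  sums <- tools::md5sum(files)
  lines <- c("# regganct run manifest",
             sprintf("package_version: %s",
                     as.character(utils::packageVersion("regganct"))),
             sprintf("seed: %d", cfg$seed),
             "config:",
             strsplit(yaml::as.yaml(cfg), "\n")[[1]],
             "checksums:",
             sprintf("  %s: %s", basename(names(sums)), unname(sums)))
  writeLines(lines, file.path(out, "run_manifest.txt"))
  invisible(NULL)
}

#' Run pipeline stages
#'
#' Executes one stage (or `"all"`) of the phantom pipeline under a
#' configuration from [load_config()]. Stages: `simulate` (write the
#' phantom dataset), `preprocess` (rigid alignment; deformable dCT for
#' test patients), `train`, `translate`, `evaluate` (similarity + ROI
#' statistics CSV), `gamma` (dose, gamma pass rates, DVH parameters
#' CSV), `report`.
#'
#' @param command stage name or `"all"`.
#' @param cfg configuration list.
#' @return invisibly, the last stage's value.
#' @export
run_pipeline <- function(command = "all", cfg = load_config()) {
  stages <- c("simulate", "preprocess", "train", "translate", "evaluate",
              "gamma", "report")
  if (!command %in% c(stages, "all"))
    stop(sprintf("unknown command '%s'; valid: %s", command,
                 paste(c(stages, "all"), collapse = ", ")))
  todo <- if (command == "all") stages else command
  res <- NULL
  for (st in todo) {
    message("[regganct] stage: ", st)
    res <- switch(st,
                  simulate = pipeline_simulate(cfg),
                  preprocess = pipeline_preprocess(cfg),
                  train = pipeline_train(cfg),
                  translate = pipeline_translate(cfg),
                  evaluate = pipeline_evaluate(cfg),
                  gamma = pipeline_gamma(cfg),
                  report = pipeline_report(cfg))
  }
  write_run_manifest(cfg)
  invisible(res)
}
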