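#' Configuration of a full benchmark experiment
#'
#' Bundles the phantom, dilation, model and saliency settings together with
#' the cohort sizes, the attribution methods to evaluate, and the output
#' directory. The training cohort (`cohort_n` subjects, split 80/20 into
#' train/validation) is shared by the paired models: the non-dilated (ND)
#' variant trains on the subjects as generated, the dilated (D) variant on
#' the same subjects with the age-proportional ventricular dilation applied.
#' `eval_n` additional held-out subjects are used for the ground-truth map,
#' the saliency maps and the similarity reports.
#'
#' @param phantom a [phantom_params()].
#' @param dilation a [dilation_spec()].
#' @param model a [model_config()].
#' @param saliency a [saliency_config()].
#' @param cohort_n training-cohort size (default 200).
#' @param eval_n held-out evaluation subjects (default 24).
#' @param methods method tags to evaluate; must be non-empty, from
#'   `G, IXG, MG, GB, GGC, IG, GSHAP`. Percentage tables are produced when
#'   `MG` (the baseline) is among them.
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param out_dir output directory (created if missing).
#' @param write_volumes also write per-subject NIfTI volumes (default TRUE).
#' @return an object of class `vb_experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_params(),
                              dilation = dilation_spec(),
                              model = model_config(),
                              saliency = saliency_config(),
                              cohort_n = 200,
                              eval_n = 24,
                              methods = c("G", "IXG", "MG", "GB", "GGC",
                                          "IG", "GSHAP"),
                              seed = 1,
                              out_dir = tempfile("ventbench-"),
                              write_volumes = TRUE) {
  all_methods <- c("G", "IXG", "MG", "GB", "GGC", "IG", "GSHAP")
  if (length(methods) == 0L || !all(methods %in% all_methods)) {
    stop("`methods` must be a non-empty subset of ",
         paste(all_methods, collapse = ", "), call. = FALSE)
  }
  stopifnot(cohort_n >= 5, eval_n >= 1,
            model$input_size == phantom$grid_size)
  structure(list(phantom = phantom, dilation = dilation, model = model,
                 saliency = saliency, cohort_n = as.integer(cohort_n),
                 eval_n = as.integer(eval_n), methods = methods,
                 seed = as.integer(seed), out_dir = out_dir,
                 write_volumes = isTRUE(write_volumes)),
            class = "vb_experiment_config")
}

#' Desk-scale experiment configuration
#'
#' The configuration used for the package's own paired-model replication:
#' 200 training phantoms at 32^3 voxels plus 12 held-out subjects, a slimmed
#' network (filters 4/8/16/32, dense width 64) sized for single-CPU training,
#' learning rate 1e-3 and at most 6 epochs. These sizes are the package's
#' reference study conditions; any field can be overridden through `...`
#' (passed to [experiment_config()]).
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @param ... overrides forwarded to [experiment_config()].
#' @return an [experiment_config()] object.
#' @export
desk_experiment_config <- function(seed = 1, out_dir = tempfile("ventbench-"),
                                   ...) {
  experiment_config(
    phantom = phantom_params(),
    dilation = dilation_spec(),
    model = model_config(input_size = 32, conv_filters = c(4, 8, 16, 32),
                         dense_width = 64, learning_rate = 1e-3,
                         max_epochs = 6, batch_size = 8, seed = 5),
    saliency = saliency_config(),
    cohort_n = 200, eval_n = 12,
    seed = seed, out_dir = out_dir, write_volumes = FALSE, ...)
}

#' Run the full paired-model saliency benchmark
#'
#' Generates the phantom cohort, applies the age-proportional dilation,
#' trains the paired ND/D regressors on identical subjects (differing only by
#' the perturbation), synthesizes the surrogate ground truth from the
#' held-out pairs, computes cohort-average saliency densities for every
#' requested method under both models (ND maps on unperturbed volumes, D maps
#' on perturbed ones), and scores everything against the ground truth. All
#' artifacts are written under `config$out_dir`; the run is a pure function
#' of the configuration (including its seed).
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress.
#' @return a `vb_experiment` bundle: configuration, cohort table, trained
#'   models, ground truth, average saliency maps, similarity reports and
#'   percentage/delta tables, plus the paths of the written artifacts.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "vb_experiment_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- "cohort generation"
  bundle <- tryCatch({
    t0 <- Sys.time()
    say("[%s] generating %d + %d phantoms", format(t0, "%H:%M:%S"),
        config$cohort_n, config$eval_n)
    cohort <- generate_cohort(config$cohort_n + config$eval_n, config$phantom,
                              seed = derive_seed(config$seed, "cohort"))
    train_pool <- cohort[seq_len(config$cohort_n)]
    eval_set <- cohort[config$cohort_n + seq_len(config$eval_n)]
    parts <- split_cohort(train_pool, c(train = 0.8, val = 0.2),
                          seed = derive_seed(config$seed, "split"))

    stage <- "perturbation"
    cohort_ages <- vapply(train_pool, function(s) s$age, numeric(1))
    coef_of <- function(s) dilation_coefficient(s$age, cohort_ages,
                                                config$dilation)
    perturb_subject <- function(s) {
      res <- dilate_ventricles(s$volume, s$labels, coef_of(s),
                               seed = derive_seed(config$seed,
                                                  paste0("dilate-",
                                                         s$subject_id)))
      out <- s
      out$volume <- res$volume
      out$labels <- res$labels
      out
    }
    say("applying ventricular dilation")
    parts_d <- lapply(parts, function(g) lapply(g, perturb_subject))
    eval_d <- lapply(eval_set, perturb_subject)

    stage <- "training ND model"
    say("training ND model (%d train / %d val)",
        length(parts$train), length(parts$val))
    cfg_nd <- config$model
    m_nd <- train_model(build_model(cfg_nd), parts$train, parts$val,
                        variant = "ND", verbose = verbose)
    stage <- "training D model"
    say("training D model (paired subjects, perturbed)")
    m_d <- train_model(build_model(cfg_nd), parts_d$train, parts_d$val,
                       variant = "D", verbose = verbose)

    stage <- "ground truth"
    gt <- synthesize_ground_truth(Map(function(p, o) list(p$volume, o$volume),
                                      eval_d, eval_set))

    stage <- "saliency"
    baselines <- lapply(eval_set, function(s) s$volume$data)
    avg_maps <- list(ND = list(), D = list())
    for (variant in c("ND", "D")) {
      mdl <- if (variant == "ND") m_nd else m_d
      subjects <- if (variant == "ND") eval_set else eval_d
      for (meth in config$methods) {
        say("attributing %s / %s over %d subjects", variant, meth,
            length(subjects))
        maps <- lapply(seq_along(subjects), function(i) {
          s <- subjects[[i]]
          sc <- config$saliency
          sc$seed <- derive_seed(config$seed,
                                 paste0("sal-", variant, "-", meth, "-", i))
          att <- compute_attribution(meth, mdl, s$volume,
                                     mask = brain_mask(s$labels),
                                     baselines = baselines, config = sc)
          # a method may legitimately attribute nothing for one subject
          # (e.g. a fully gated GradCAM map); such maps carry no density
          if (sum(abs(att$data)) == 0) NULL else normalize_to_density(att)
        })
        maps <- Filter(Negate(is.null), maps)
        if (length(maps) == 0L) {
          stop(sprintf("method %s attributed nothing on every %s subject",
                       meth, variant), call. = FALSE)
        }
        avg_maps[[variant]][[meth]] <- cohort_average_map(maps)
      }
    }

    stage <- "scoring"
    score_all <- function(maps) {
      do.call(rbind, lapply(config$methods, function(meth) {
        evaluate_method(maps[[meth]], gt, method = meth)
      }))
    }
    reports <- list(ND = score_all(avg_maps$ND), D = score_all(avg_maps$D))
    pct <- if ("MG" %in% config$methods) {
      list(ND = percentage_table(reports$ND), D = percentage_table(reports$D))
    } else NULL
    measures <- c("dc", "nmi", "nss", "cc", "sim")
    delta <- reports$ND[, "method", drop = FALSE]
    for (m in measures) {
      v0 <- reports$ND[[m]]
      delta[[m]] <- ifelse(v0 == 0, NA_real_,
                           100 * (reports$D[[m]] - v0) / abs(v0))
    }
    mae <- c(ND = evaluate_mae(m_nd, eval_set), D = evaluate_mae(m_d, eval_d))

    stage <- "artifact writing"
    ids <- vapply(cohort, function(s) s$subject_id, character(1))
    split_of <- rep("eval", length(cohort))
    for (nm in names(parts)) {
      split_of[ids %in% vapply(parts[[nm]], function(s) s$subject_id,
                               character(1))] <- nm
    }
    tab <- data.frame(subject_id = ids,
                      age = vapply(cohort, function(s) s$age, numeric(1)),
                      split = split_of,
                      coefficient = vapply(cohort, coef_of, numeric(1)),
                      stringsAsFactors = FALSE)
    paths <- write_experiment_artifacts(config, tab, cohort,
                                        c(parts_d$train, parts_d$val, eval_d),
                                        m_nd, m_d, gt, avg_maps, reports, pct,
                                        delta, mae)
    say("done in %.1f min", as.numeric(difftime(Sys.time(), t0, units = "mins")))
    structure(list(config = config, cohort_table = tab,
                   models = list(ND = m_nd, D = m_d), ground_truth = gt,
                   avg_maps = avg_maps, reports = reports, pct = pct,
                   delta = delta, mae = mae, paths = paths),
              class = "vb_experiment")
  }, error = function(e) {
    stop(sprintf("experiment failed during %s: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  bundle
}

write_experiment_artifacts <- function(config, tab, originals, perturbed,
                                       m_nd, m_d, gt, avg_maps, reports, pct,
                                       delta, mae) {
  out <- config$out_dir
  p <- list(cohort = file.path(out, "cohort.csv"))
  write_cohort_table(tab, p$cohort)
  p$ground_truth <- file.path(out, "ground_truth.nii.gz")
  write_volume(volume(gt$density), p$ground_truth)
  p$checkpoints <- c(ND = file.path(out, "model_ND.rds"),
                     D = file.path(out, "model_D.rds"))
  save_checkpoint(m_nd, p$checkpoints[["ND"]])
  save_checkpoint(m_d, p$checkpoints[["D"]])
  for (variant in names(avg_maps)) {
    for (meth in names(avg_maps[[variant]])) {
      f <- file.path(out, sprintf("saliency_%s_%s.nii.gz", variant, meth))
      write_volume(volume(avg_maps[[variant]][[meth]]$density), f)
      p$saliency <- c(p$saliency, f)
    }
  }
  p$reports <- c(ND = file.path(out, "report_ND.csv"),
                 D = file.path(out, "report_D.csv"))
  write.csv(reports$ND, p$reports[["ND"]], row.names = FALSE)
  write.csv(reports$D, p$reports[["D"]], row.names = FALSE)
  if (!is.null(pct)) {
    p$pct <- c(ND = file.path(out, "pct_vs_MG_ND.csv"),
               D = file.path(out, "pct_vs_MG_D.csv"))
    write.csv(pct$ND, p$pct[["ND"]], row.names = FALSE)
    write.csv(pct$D, p$pct[["D"]], row.names = FALSE)
  }
  p$delta <- file.path(out, "delta_D_vs_ND.csv")
  write.csv(delta, p$delta, row.names = FALSE)
  p$mae <- file.path(out, "mae.csv")
  write.csv(data.frame(variant = names(mae), mae_years = as.numeric(mae)),
            p$mae, row.names = FALSE)
  if (config$write_volumes) {
    vd <- file.path(out, "volumes")
    dir.create(vd, showWarnings = FALSE)
    for (s in originals) {
      write_volume(s$volume, file.path(vd, paste0(s$subject_id, "_T1.nii.gz")))
      write_volume(s$labels, file.path(vd, paste0(s$subject_id, "_aseg.nii.gz")))
    }
    for (s in perturbed) {
      write_volume(s$volume,
                   file.path(vd, paste0(s$subject_id, "_T1_dilated.nii.gz")))
      write_volume(s$labels,
                   file.path(vd, paste0(s$subject_id, "_aseg_dilated.nii.gz")))
    }
    p$volumes_dir <- vd
  }
  p
}

#' Render a Markdown summary of an experiment bundle
#'
#' @param bundle a `vb_experiment` from [run_experiment()].
#' @param path optional file to write the document to.
#' @return the Markdown document as a character scalar (invisibly if written).
#' @export
report_markdown <- function(bundle, path = NULL) {
  required <- c("config", "reports", "delta", "mae")
  missing <- required[!vapply(required, function(n) !is.null(bundle[[n]]),
                              logical(1))]
  if (!inherits(bundle, "vb_experiment") || length(missing) > 0L) {
    stop("incomplete experiment bundle; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cfg <- bundle$config
  md_table <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    fmt <- df
    fmt[num] <- lapply(df[num], function(x) sprintf("%.4f", x))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
    paste(c(header, sep, rows), collapse = "\n")
  }
  doc <- paste0(
    "# Saliency benchmark report\n\n",
    sprintf(paste0("Configuration: %d training phantoms + %d held-out, grid ",
                   "%d^3, methods %s, seed %d.\n\n"),
            cfg$cohort_n, cfg$eval_n, cfg$phantom$grid_size,
            paste(cfg$methods, collapse = "/"), cfg$seed),
    sprintf("Held-out MAE: ND %.2f y, D %.2f y.\n\n",
            bundle$mae[["ND"]], bundle$mae[["D"]]),
    "## Similarity to ground truth (D model)\n\n",
    md_table(bundle$reports$D), "\n\n",
    "## Similarity to ground truth (ND model)\n\n",
    md_table(bundle$reports$ND), "\n\n",
    if (!is.null(bundle$pct)) {
      paste0("## Percentage difference vs MG (D model)\n\n",
             md_table(bundle$pct$D), "\n\n")
    } else "",
    "## D vs ND percentage change\n\n",
    md_table(bundle$delta), "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

#' @export
print.vb_experiment <- function(x, ...) {
  cat(sprintf("<vb_experiment> %d+%d phantoms, methods %s, out_dir %s\n",
              x$config$cohort_n, x$config$eval_n,
              paste(x$config$methods, collapse = "/"), x$config$out_dir))
  invisible(x)
}
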