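# Shared fixtures. Heavy trained-model experiments are cached in this
# environment so that the acceptance checks that share one study
# (parameter recovery, attention localization, multi-plane comparison)
# compute it once per test run.
.fixture_cache <- new.env(parent = emptyenv())

# A fast, clean config for unit tests: no clutter/noise unless asked.
quiet_config <- function(...) {
  phantom_config(clutter_count = 0L, noise_sd = 0, center_jitter_sd = 0, ...)
}

# Prepared single-plane dataset for quick training tests.
tiny_train_fixture <- function() {
  if (!is.null(.fixture_cache$tiny_train)) return(.fixture_cache$tiny_train)
  cfg <- phantom_config(center_jitter_sd = 1)
  man <- generate_cohort(cfg, 60, seed = 77)
  sp <- split_dataset(man, seed = 77)
  prep <- function(part) {
    ids <- sp$subject_id[sp$partition == part]
    prepare_dataset(man[man$subject_id %in% ids, ], planes = "axial",
                    n_slices = 1L, size = 64L, seed = 77)
  }
  .fixture_cache$tiny_train <- list(
    config = cfg,
    train = prep("train"), val = prep("val"), test = prep("test")
  )
  .fixture_cache$tiny_train
}

# One 400-subject cohort (70/10/20 split) shared by the desk-scale study;
# the five replicates vary the network-initialization and training seeds.
accept_cohort <- function() {
  if (!is.null(.fixture_cache$cohort)) return(.fixture_cache$cohort)
  cfg <- phantom_config()
  man <- generate_cohort(cfg, 400L, seed = 1001L)
  sp <- split_dataset(man, seed = 1001L)
  prep <- function(part) {
    ids <- sp$subject_id[sp$partition == part]
    prepare_dataset(man[man$subject_id %in% ids, ], n_slices = 3L,
                    size = 64L, seed = 1001L)
  }
  .fixture_cache$cohort <- list(
    config = cfg, manifest = man,
    train = prep("train"), val = prep("val"), test = prep("test"))
  .fixture_cache$cohort
}

# The shared desk-scale study: tiny backbone, 64 px, 3 slices, three
# planes, 400 subjects split 70/10/20, 500 optimizer steps; five seeded
# replicates. Returns per-replicate held-out metrics, localization rates
# and per-plane MAEs.
accept_study <- function(n_seeds = 5L) {
  key <- paste0("study", n_seeds)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  out <- purrr::map(seq_len(n_seeds), function(s) run_accept_replicate(s))
  .fixture_cache[[key]] <- out
  out
}

run_accept_replicate <- function(s, iterations = 500L) {
  co <- accept_cohort()
  cfg <- co$config; man <- co$manifest
  train_d <- co$train; val_d <- co$val; test_d <- co$test
  model <- build_multiplane_model(
    backbone_spec("tiny", in_channels = 3L, input_size = 64L),
    seed = 2000L + s)
  ck <- train_model(model, train_d,
                    train_config("desk", iterations = iterations,
                                 eval_every = 100L, seed = 3000L + s),
                    val_data = val_d)
  pred <- multiplane_predict(ck$model, test_d)

  # attention localization on held-out subjects, all three planes
  test_man <- man[man$subject_id %in% test_d$subject_id, ]
  hits <- unlist(purrr::map(seq_len(nrow(test_d)), function(i) {
    subj <- test_man$subject[[match(test_d$subject_id[i],
                                    test_man$subject_id)]]
    purrr::map_lgl(names(ck$model$planes), function(pl) {
      fwd <- forward_dual(ck$model$planes[[pl]], test_d[[paste0("slab_", pl)]][[i]])
      localization_hit(fwd$heatmap, subj$truth_masks[[pl]], dilate_px = 5)
    })
  }))

  plane_mae <- purrr::map_dbl(
    setNames(names(ck$model$planes), names(ck$model$planes)),
    function(pl) mae_days(pred$y_true, pred[[paste0("y_pred_", pl)]]))

  list(
    seed = s,
    r2 = r2_score(pred$y_true, pred$y_pred),
    mae = mae_days(pred$y_true, pred$y_pred),
    label_range = diff(cfg$age_range),
    loc_rate = mean(hits),
    plane_mae = plane_mae,
    multi_mae = mae_days(pred$y_true, pred$y_pred),
    checkpoint = ck,
    config = cfg
  )
}

# Single-plane checkpoint trained on the tiny fixture, cached per run.
tiny_checkpoint <- function() {
  if (!is.null(.fixture_cache$tiny_ck)) return(.fixture_cache$tiny_ck)
  fx <- tiny_train_fixture()
  model <- build_multiplane_model(
    backbone_spec("tiny", in_channels = 1, input_size = 64),
    planes = "axial", seed = 21)
  cfg <- train_config("desk", iterations = 300L, eval_every = 100L, seed = 31)
  .fixture_cache$tiny_ck <- train_model(model, fx$train, cfg,
                                        val_data = fx$val)
  .fixture_cache$tiny_ck
}

# Heavy-clutter paired comparison: dual-branch vs global-only on the same
# cohort, five paired training seeds, single (axial) plane.
clutter_comparison <- function(n_seeds = 5L) {
  key <- paste0("clutter", n_seeds)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- phantom_config(clutter_count = 16L)
  man <- generate_cohort(cfg, 150L, seed = 5001L)
  sp <- split_dataset(man, seed = 5001L)
  prep <- function(part) {
    ids <- sp$subject_id[sp$partition == part]
    prepare_dataset(man[man$subject_id %in% ids, ], planes = "axial",
                    n_slices = 3L, size = 64L, seed = 5001L)
  }
  train_d <- prep("train"); val_d <- prep("val"); test_d <- prep("test")
  run <- function(mode, s) {
    model <- build_multiplane_model(
      backbone_spec("tiny", in_channels = 3L, input_size = 64L),
      planes = "axial", mode = mode, seed = 6000L + s)
    ck <- train_model(model, train_d,
                      train_config("desk", iterations = 250L,
                                   eval_every = 125L, seed = 6500L + s),
                      val_data = val_d)
    pred <- multiplane_predict(ck$model, test_d)
    mae_days(pred$y_true, pred$y_pred)
  }
  out <- list(
    dual_mae = purrr::map_dbl(seq_len(n_seeds), ~ run("dual", .x)),
    global_mae = purrr::map_dbl(seq_len(n_seeds), ~ run("global_only", .x))
  )
  .fixture_cache[[key]] <- out
  out
}

# Domain-shift study: the first replicate's trained model, fine-tuned on a
# contrast/noise/ghosting-degraded cohort with the 20% protocol, across
# five fine-tuning seeds.
finetune_study <- function(n_seeds = 5L) {
  key <- paste0("finetune", n_seeds)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  base <- accept_study(5L)[[1]]$checkpoint
  cfg <- phantom_config()
  site <- generate_cohort(cfg, 100L, seed = 7001L, site_tag = "external")
  site <- degrade_cohort(site, contrast_scale = 1.6, extra_noise_sd = 0.12,
                         ghosting_amplitude = 0.15, site_tag = "external",
                         seed = 7002L)
  res <- purrr::map(seq_len(n_seeds), function(s) {
    ft <- finetune(base, site,
                   finetune_config("desk", max_epochs = 15L,
                                   seed = 7100L + s))
    ft$comparison
  })
  out <- list(
    delta_mae = purrr::map_dbl(res, ~ .x$delta_mae[2]),
    delta_r2 = purrr::map_dbl(res, ~ .x$delta_r2[2]),
    comparisons = res
  )
  .fixture_cache[[key]] <- out
  out
}
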