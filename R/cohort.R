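#' Generate a phantom cohort for a weak-label recovery study
#'
#' Builds `n_cases` synthetic "cases" (one scene each), renders their
#' pseudo-IHC images, derives per-ROI stain masks with the full mask
#' pipeline, samples balanced ROI positions (every plaque-component-centred
#' window plus an equal number of amyloid-free windows), extracts labeled ROI
#' samples, and splits them strictly at case level. Scenes are kept so that
#' held-out slides can be segmented and scored against their ground truth.
#'
#' The default dimensions define a compact study: 256 x 256 px scenes with a
#' 16-channel compressed band set and ~19 plaques per case, giving roughly
#' 150 positive and 150 negative ROIs over 8 cases with a 4/2/2
#' train/validation/test split.
#'
#' @param n_cases Number of cases.
#' @param height,width Scene size in pixels.
#' @param n_plaques Plaques per scene.
#' @param axis Wavenumber axis (default: 16 channels spanning the instrument
#'   range).
#' @param spectral A [spectral_model()].
#' @param mask_cfg A [mask_config()].
#' @param split Named counts `c(train =, val =, test =)` summing to
#'   `n_cases`.
#' @param seed Master seed; per-case and per-stage seeds derive from it.
#' @return A list of class `phantom_cohort` with `samples`, `splits`,
#'   `assignment`, `scenes` (per case: cube, truth, ihc, origin lists) and
#'   `balance`.
#' @export
phantom_cohort <- function(n_cases = 8, height = 256, width = 256,
                           n_plaques = 19,
                           axis = make_wavenumber_axis(1800, 948, 56.8),
                           spectral = spectral_model(),
                           mask_cfg = mask_config(),
                           split = c(train = 4, val = 2, test = 2),
                           seed = 1L) {
  stopifnot(sum(split) == n_cases)
  case_ids <- sprintf("case%02d", seq_len(n_cases))
  assignment <- stats::setNames(rep(names(split), split), case_ids)
  scenes <- list()
  samples <- list()
  for (k in seq_len(n_cases)) {
    cid <- case_ids[k]
    sc <- generate_scene(height, width, n_plaques, spectral,
                         seed = derive_seed(seed, paste0("scene", k)),
                         axis = axis)
    ihc <- render_pseudo_ihc(sc$truth, stain_params(
      seed = derive_seed(seed, paste0("stain", k))))
    pos <- sample_roi_positions(sc$truth, mask = sc$truth$plaque_mask,
                                seed = derive_seed(seed, paste0("roi", k)))
    origins <- rbind(pos$positive, pos$negative)
    roi_masks <- lapply(seq_len(nrow(origins)), function(i) {
      r <- origins[i, 1]; c <- origins[i, 2]
      crop <- ihc[r:(r + 63), c:(c + 63), , drop = FALSE]
      ihc_mask_pipeline(crop, mask_cfg)
    })
    smp <- suppressMessages(
      extract_rois(sc$cube, roi_masks, origins, case_id = cid,
                   threshold = mask_cfg$positive_fraction_threshold))
    samples <- c(samples, smp)
    scenes[[cid]] <- list(cube = sc$cube, truth = sc$truth, ihc = ihc,
                          origins = origins)
  }
  splits <- split_by_case(samples, assignment)
  structure(list(samples = samples, splits = splits,
                 assignment = assignment, scenes = scenes,
                 balance = class_balance(splits), axis = axis, seed = seed),
            class = "phantom_cohort")
}

#' Run the full weak-label recovery study on a phantom cohort
#'
#' Trains the network on the cohort's training split, selects the epoch with
#' the best validation specificity, evaluates ROI-level classification on the
#' held-out test cases, segments the held-out slides, and scores the
#' per-component plaque hit rate and purification metrics against the scene
#' ground truth.
#'
#' @param cohort A [phantom_cohort()].
#' @param cfg A [train_config()]; the default here is the reduced study
#'   configuration: encoder width 6, Adam at learning rate 5e-3 annealed by
#'   0.9 every 4 epochs (the full-scale schedule's 50/500 proportion), batch
#'   5, background-loss weight 5, a frozen output bias initialized at
#'   `qlogis(0.02)`, and at most 40 epochs.
#' @param p A [transfer_params()].
#' @param binarize_threshold Threshold for hit-rate / purification scoring.
#' @param restarts Maximum number of training restarts. Short-budget weak
#'   supervision is sensitive to the optimization trajectory: some seeds
#'   settle with the background activation on the wrong side of the lower
#'   transfer bound. Each restart trains with a different derived seed (the
#'   first uses the configured seed itself); restarting stops as soon as the
#'   selected epoch reaches specificity >= 0.9 and sensitivity >= 0.8 on the
#'   validation split, and otherwise the restart with the best validation
#'   specificity (then F1) is kept. All selection happens on validation
#'   data only.
#' @param verbose Print per-epoch progress.
#' @return A list with the `fit`, selected `model`, `test_eval` (ROI-level),
#'   per-slide `hit` and `seg_eval` results.
#' @export
run_phantom_study <- function(cohort,
                              cfg = train_config(lr0 = 5e-3, decay = 0.9,
                                                 decay_every = 4,
                                                 max_epochs = 40,
                                                 patience = 40,
                                                 batch_size = 5,
                                                 lambda_bg = 5,
                                                 optimizer = "adam",
                                                 base_features = 6,
                                                 freeze_out_bias = TRUE,
                                                 out_bias_init =
                                                   stats::qlogis(0.02),
                                                 seed = cohort$seed),
                              p = transfer_params(),
                              binarize_threshold = 0.5,
                              restarts = 2,
                              verbose = FALSE) {
  fit <- NULL; best <- c(-Inf, -Inf)
  for (r in seq_len(max(restarts, 1))) {
    cfg_r <- cfg
    if (r > 1) cfg_r$seed <- derive_seed(cfg$seed, paste0("restart", r))
    fit_r <- train_compsegnet(cohort$splits$train, cohort$splits$val, cfg_r,
                              p, verbose = verbose)
    m <- fit_r$metrics[fit_r$selected, ]
    score <- c(m$specificity, if (is.na(m$f1)) -Inf else m$f1)
    if (is.null(fit) || score[1] > best[1] ||
        (score[1] == best[1] && score[2] > best[2])) {
      fit <- fit_r; best <- score
    }
    if (!is.na(m$specificity) && m$specificity >= 0.9 &&
        !is.na(m$sensitivity) && m$sensitivity >= 0.8) break
  }
  model <- checkpoint_model(fit)
  test_eval <- evaluate_roi_set(model, cohort$splits$test, p,
                                fit$class_weights, cfg$lambda_bg)
  test_cases <- names(cohort$assignment)[cohort$assignment == "test"]
  preds <- list(); truths <- list(); hits <- integer(0); comps <- integer(0)
  act_maps <- list()
  for (cid in test_cases) {
    sc <- cohort$scenes[[cid]]
    act <- segment_wsi(model, sc$cube)
    act_maps[[cid]] <- act
    pred <- binarize_activation(act, binarize_threshold)
    hr <- component_hit_rate(pred, sc$truth$plaque_labels)
    hits <- c(hits, hr$n_hit); comps <- c(comps, hr$n_components)
    preds[[cid]] <- pred
    truths[[cid]] <- sc$truth$plaque_mask
  }
  list(fit = fit, model = model, test_eval = test_eval,
       activation_maps = act_maps,
       hit = list(hit_rate = sum(hits) / sum(comps),
                  n_hit = sum(hits), n_components = sum(comps)),
       seg_eval = evaluate_segmentation(preds, truths))
}
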