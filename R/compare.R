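#' Training recipe for small synthetic runs
#'
#' The full-scale defaults of [train_config()] suit large backbones
#' trained for many epochs; the ~25k-parameter reference detector on a
#' few hundred 96 px scenes needs a shorter, hotter schedule to reach a
#' useful operating point. This helper bundles the package's standard
#' small-run recipe (see the methods vignette for the reasoning).
#'
#' @param seed Training seed.
#' @param epochs Number of epochs; default 25.
#' @param base_lr Peak learning rate; default 0.04.
#' @param batch_size Images per SGD step; default 4 (many small steps
#'   suit a tiny network on a few hundred images).
#' @return A [train_config()].
#' @export
small_run_config <- function(seed = 1L, epochs = 25, base_lr = 0.04,
                             batch_size = 4) {
  train_config(epochs = epochs, batch_size = batch_size, base_lr = base_lr,
               momentum = 0.9, weight_decay = 5e-4, lr_gamma = 0.1,
               seed = seed)
}

#' Train and evaluate several loss schemes under one seed
#'
#' For each scheme a detector is trained from the same initialization
#' on the same data order (everything but the loss is held fixed by the
#' shared seed) and evaluated on the test split. This is the package's
#' analogue of comparing a detector trained with plain cross-entropy
#' against its class-aware retraining.
#'
#' @param train_ds,test_ds `detection_dataset` splits.
#' @param census Training-split [class_census()].
#' @param schemes Character vector of reweight schemes to run.
#' @param seed Shared seed for initialization and data order.
#' @param eta,beta Reweighting hyper-parameters.
#' @param train_cfg A [train_config()]; default [small_run_config()].
#' @param score_threshold,nms_iou,iou_threshold Evaluation settings.
#' @return An object of class `scheme_comparison`: `per_class` (long
#'   tibble `scheme, class, ap, n_gt`), `summary` (`scheme, map`),
#'   `models` (the trained detectors), `census`.
#' @export
compare_schemes <- function(train_ds, test_ds, census,
                            schemes = c("none", "class_aware"),
                            seed = 1L, eta = 4, beta = 2,
                            train_cfg = small_run_config(seed),
                            score_threshold = 0.05, nms_iou = 0.45,
                            iou_threshold = 0.5) {
  train_cfg$seed <- as.integer(seed)
  runs <- purrr::map(schemes, function(sch) {
    lcfg <- loss_config(reweight = reweight_config(sch, eta = eta, beta = beta))
    model <- train_detector(train_ds, census = census, loss_cfg = lcfg,
                            train_cfg = train_cfg)
    eval <- evaluate_detector(model, test_ds, score_threshold = score_threshold,
                              nms_iou = nms_iou, iou_threshold = iou_threshold,
                              classes = census$species)
    list(model = model, eval = eval)
  })
  names(runs) <- schemes
  per_class <- purrr::map_dfr(schemes, function(sch) {
    dplyr::mutate(runs[[sch]]$eval$per_class, scheme = sch, .before = 1)
  })
  summary <- purrr::map_dfr(schemes, function(sch) {
    tibble::tibble(scheme = sch, map = runs[[sch]]$eval$map)
  })
  structure(list(per_class = per_class, summary = summary,
                 models = purrr::map(runs, "model"), census = census),
            class = "scheme_comparison")
}

#' Mean AP over the k rarest species
#'
#' Rarity is judged by the census: the k species with the fewest
#' training instances (ties to the later census rank). Classes without
#' test ground truths are excluded from the mean.
#'
#' @param per_class A per-class AP tibble (`class`, `ap`, optionally
#'   `scheme`).
#' @param census The training [class_census()].
#' @param k Number of rare species; default 3.
#' @return A tibble with one row (or one per scheme): `rare_map`,
#'   `rare_classes`.
#' @export
rare_class_map <- function(per_class, census, k = 3) {
  rare <- census$species[order(census$count, seq_len(nrow(census)))][seq_len(k)]
  sub <- per_class[per_class$class %in% rare & !is.na(per_class$ap), , drop = FALSE]
  if ("scheme" %in% names(sub)) {
    out <- dplyr::summarise(dplyr::group_by(sub, .data$scheme),
                            rare_map = mean(.data$ap), .groups = "drop")
  } else {
    out <- tibble::tibble(rare_map = mean(sub$ap))
  }
  out$rare_classes <- paste(rare, collapse = ",")
  out
}

#' @export
print.scheme_comparison <- function(x, ...) {
  cat("<scheme_comparison> schemes:", paste(x$summary$scheme, collapse = ", "), "\n")
  print(x$summary)
  invisible(x)
}
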