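#' Configuration of the multibox loss family
#'
#' @param alpha Weight of the localization part in the combined loss;
#'   default 1 (the SSD convention, also used for the reweighted
#'   objectives).
#' @param reweight A [reweight_config()] selecting the imbalance scheme.
#' @param normalization `"by_matched_N"` (default): divide both parts by
#'   N, the matched-default count; `"by_total_n"`: divide by the number
#'   of contributing defaults (positives plus mined negatives).
#' @param hard_negative_ratio Background defaults contributing to the
#'   classification loss are limited to `ratio * N` hardest negatives
#'   (highest cross-entropy). Default 3; 0 lets every negative
#'   contribute. Without mining the background term swamps every scheme.
#' @param focal_gamma Focusing exponent of the focal loss; default 2.
#'   Used only when the reweight scheme is `"focal"` or by
#'   [focal_loss()] directly. `gamma = 0` recovers cross-entropy.
#' @param encoding Offset-encoding variant the targets were built with.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(alpha = 1, reweight = reweight_config(),
                        normalization = c("by_matched_N", "by_total_n"),
                        hard_negative_ratio = 3, focal_gamma = 2,
                        encoding = c("plain", "ssd_standard")) {
  normalization <- match.arg(normalization)
  encoding <- match.arg(encoding)
  stopifnot(alpha >= 0, hard_negative_ratio >= 0, focal_gamma >= 0,
            inherits(reweight, "reweight_config"))
  structure(list(alpha = alpha, reweight = reweight,
                 normalization = normalization,
                 hard_negative_ratio = hard_negative_ratio,
                 focal_gamma = focal_gamma, encoding = encoding),
            class = "loss_config")
}

#' Bundle predictions and targets for loss evaluation
#'
#' @param conf A `D x (K+1)` matrix of per-default class confidences on
#'   the probability simplex (rows sum to 1 within 1e-6). Column names
#'   are the class labels and must include `"background"`.
#' @param loc A `D x 4` matrix of predicted offsets, columns
#'   `(t_cx, t_cy, t_w, t_h)`.
#' @param match A [match_boxes()] result with D rows.
#' @param census Optional [class_census()]; required by the reweighted
#'   objectives.
#' @return A list of class `loss_batch`.
#' @export
loss_batch <- function(conf, loc, match, census = NULL) {
  stopifnot(is.matrix(conf), is.matrix(loc), inherits(match, "match_result"),
            nrow(conf) == nrow(match), nrow(loc) == nrow(match), ncol(loc) == 4)
  if (is.null(colnames(conf)) || !"background" %in% colnames(conf)) {
    rlang::abort("`conf` must have class-label column names including \"background\".")
  }
  if (any(abs(rowSums(conf) - 1) > 1e-6)) {
    rlang::abort("each row of `conf` must sum to 1 (probability simplex).")
  }
  missing_cls <- setdiff(unique(match$class), colnames(conf))
  if (length(missing_cls) > 0) {
    rlang::abort(paste0("`conf` lacks columns for matched classes: ",
                        paste(missing_cls, collapse = ", ")))
  }
  structure(list(conf = conf, loc = loc, match = match, census = census),
            class = "loss_batch")
}

#' SmoothL1 penalty
#'
#' `0.5 x^2` for `|x| < 1`, `|x| - 0.5` otherwise: quadratic near zero,
#' linear in the tails, continuously differentiable at `|x| = 1`.
#'
#' @param x Numeric residuals.
#' @return Non-negative values of the same length.
#' @export
smooth_l1 <- function(x) {
  ax <- abs(x)
  ifelse(ax < 1, 0.5 * x^2, ax - 0.5)
}

# derivative of smooth_l1: x clamped to [-1, 1]
smooth_l1_grad <- function(x) pmax(pmin(x, 1), -1)

.LOG_EPS <- 1e-12

# Shared decomposition of a batch into per-default contributions.
# The contributing set (positives + mined negatives) depends only on the
# predictions and the match, never on the reweighting scheme, so scheme
# swaps rescale contributions without changing which defaults count.
loss_parts <- function(batch, config) {
  match <- batch$match
  pos <- which(match$class != "background")
  neg <- which(match$class == "background")
  N <- length(pos)
  true_ix <- match(match$class, colnames(batch$conf))
  p_true <- batch$conf[cbind(seq_len(nrow(batch$conf)), true_ix)]
  clamped <- p_true < .LOG_EPS
  if (any(clamped)) {
    rlang::warn("confidence at the true class clamped to 1e-12 inside log.")
  }
  ce <- -log(pmax(p_true, .LOG_EPS))
  mined_neg <- neg
  r <- config$hard_negative_ratio
  if (r > 0) {
    keep <- min(length(neg), round(r * N))
    mined_neg <- if (keep > 0) neg[order(ce[neg], decreasing = TRUE)[seq_len(keep)]] else integer(0)
  }
  contributing <- sort(c(pos, mined_neg))
  # per-default localization sums (positives only)
  loc_sum <- numeric(nrow(match))
  if (N > 0) {
    tgt <- as.matrix(match[pos, c("t_cx", "t_cy", "t_w", "t_h")])
    res <- batch$loc[pos, , drop = FALSE] - tgt
    loc_sum[pos] <- rowSums(smooth_l1(res))
  }
  normalizer <- switch(config$normalization,
                       by_matched_N = N,
                       by_total_n = length(contributing))
  list(pos = pos, mined_neg = mined_neg, contributing = contributing,
       N = N, ce = ce, p_true = p_true, loc_sum = loc_sum,
       normalizer = normalizer, true_ix = true_ix)
}

# per-default scheme weights looked up from the census
scheme_weights <- function(match, census, rw) {
  w <- rep(1, nrow(match))
  bg <- match$class == "background"
  w[bg] <- rw$background_weight
  if (rw$scheme %in% c("class_aware", "class_balanced")) {
    if (is.null(census)) rlang::abort("this loss scheme requires a census.")
    fg_cls <- unique(match$class[!bg])
    missing_sp <- setdiff(fg_cls, census$species)
    if (length(missing_sp) > 0) {
      rlang::abort(paste0("species absent from census: ",
                          paste(missing_sp, collapse = ", ")))
    }
    wt <- weight_table(census, rw)
    w[!bg] <- wt$weight[match(match$class[!bg], wt$species)]
  }
  w
}

#' Localization loss over matched default boxes
#'
#' Sum of element-wise SmoothL1 on the four offset residuals of every
#' matched default, divided by the configured normalizer. Zero when no
#' default is matched.
#'
#' @param batch A [loss_batch()].
#' @param config A [loss_config()].
#' @return A non-negative scalar.
#' @export
localization_loss <- function(batch, config = loss_config()) {
  parts <- loss_parts(batch, config)
  if (parts$normalizer == 0) return(0)
  sum(parts$loc_sum) / parts$normalizer
}

#' Classification loss over contributing default boxes
#'
#' Cross-entropy `-log(p)` at the assigned class (background for
#' negatives), summed over positives and the mined hard negatives and
#' divided by the configured normalizer.
#'
#' @inheritParams localization_loss
#' @return A non-negative scalar.
#' @export
classification_loss <- function(batch, config = loss_config()) {
  parts <- loss_parts(batch, config)
  if (parts$normalizer == 0) return(0)
  sum(parts$ce[parts$contributing]) / parts$normalizer
}

#' Focal classification loss
#'
#' `-(1 - p)^gamma log(p)` at the assigned class, over the same
#' contributing set and normalizer as [classification_loss()].
#' `gamma = 0` reduces exactly to cross-entropy.
#'
#' @inheritParams localization_loss
#' @return A non-negative scalar.
#' @export
focal_loss <- function(batch, config = loss_config()) {
  parts <- loss_parts(batch, config)
  if (parts$normalizer == 0) return(0)
  i <- parts$contributing
  sum((1 - parts$p_true[i])^config$focal_gamma * parts$ce[i]) / parts$normalizer
}

multibox_result <- function(cls, loc, config, scheme) {
  tibble::tibble(total = cls + config$alpha * loc,
                 classification = cls, localization = loc,
                 scheme = scheme, alpha = config$alpha,
                 normalization = config$normalization)
}

#' Combined (unweighted) multibox loss
#'
#' `total = classification + alpha * localization` under a single
#' normalization; the plain objective every reweighted scheme reduces to
#' in its degenerate limit.
#'
#' @inheritParams localization_loss
#' @return A one-row tibble: `total`, `classification`, `localization`,
#'   `scheme`, `alpha`, `normalization`.
#' @export
combined_loss <- function(batch, config = loss_config()) {
  parts <- loss_parts(batch, config)
  if (parts$normalizer == 0) return(multibox_result(0, 0, config, "none"))
  cls <- sum(parts$ce[parts$contributing]) / parts$normalizer
  loc <- sum(parts$loc_sum) / parts$normalizer
  multibox_result(cls, loc, config, "none")
}

reweighted_loss <- function(batch, config, scheme) {
  rw <- config$reweight
  rw$scheme <- scheme
  parts <- loss_parts(batch, config)
  if (parts$normalizer == 0) return(multibox_result(0, 0, config, scheme))
  w <- scheme_weights(batch$match, batch$census, rw)
  cls <- sum((w * parts$ce)[parts$contributing]) / parts$normalizer
  loc <- sum(w * parts$loc_sum) / parts$normalizer
  multibox_result(cls, loc, config, scheme)
}

#' Class-aware multibox loss
#'
#' Every matched default's classification and localization contributions
#' are scaled by the class-aware weight of its assigned ground truth's
#' species (`(1 - ns/n)/(1 - (ns/n)^eta)`); background contributions are
#' scaled by the background weight. With `eta = 1` all weights are 1 and
#' the result equals [combined_loss()] exactly.
#'
#' @inheritParams localization_loss
#' @return A one-row tibble as in [combined_loss()].
#' @export
class_aware_loss <- function(batch, config = loss_config(reweight = reweight_config("class_aware"))) {
  reweighted_loss(batch, config, "class_aware")
}

#' Class-balanced detection objective
#'
#' The class-balanced weight `(1 - beta)/(1 - beta^ny)` of each
#' instance's species multiplies both its classification and (via
#' `alpha`) its localization term, extending the classification-only
#' class-balanced loss to detection. With every `ny = 1` the weights are
#' 1 and the result equals [combined_loss()].
#'
#' @inheritParams localization_loss
#' @return A one-row tibble as in [combined_loss()].
#' @export
class_balanced_objective <- function(batch, config = loss_config(reweight = reweight_config("class_balanced"))) {
  reweighted_loss(batch, config, "class_balanced")
}

#' Evaluate the configured multibox objective
#'
#' Dispatches on the reweight scheme: `"none"` gives [combined_loss()],
#' `"class_aware"` and `"class_balanced"` the reweighted objectives, and
#' `"focal"` pairs the focal classification term with the unweighted
#' localization loss.
#'
#' @inheritParams localization_loss
#' @return A one-row tibble as in [combined_loss()].
#' @export
multibox_loss <- function(batch, config = loss_config()) {
  scheme <- config$reweight$scheme
  switch(scheme,
    none = combined_loss(batch, config),
    class_aware = class_aware_loss(batch, config),
    class_balanced = class_balanced_objective(batch, config),
    focal = {
      parts <- loss_parts(batch, config)
      if (parts$normalizer == 0) return(multibox_result(0, 0, config, "focal"))
      i <- parts$contributing
      cls <- sum((1 - parts$p_true[i])^config$focal_gamma * parts$ce[i]) / parts$normalizer
      loc <- sum(parts$loc_sum) / parts$normalizer
      multibox_result(cls, loc, config, "focal")
    })
}

# Loss + gradients on unnormalized logits, used by the trainer.
# conf_logits: D x (K+1); loc_pred: D x 4. Returns the loss parts and
# d(loss)/d(logits), d(loss)/d(loc_pred).
multibox_loss_grad <- function(conf_logits, loc_pred, match, census, config) {
  rmax <- conf_logits[cbind(seq_len(nrow(conf_logits)),
                            max.col(conf_logits, ties.method = "first"))]
  z <- conf_logits - rmax
  ez <- exp(z)
  p <- ez / rowSums(ez)
  colnames(p) <- colnames(conf_logits)
  batch <- loss_batch(p, loc_pred, match, census)
  parts <- loss_parts(batch, config)
  scheme <- config$reweight$scheme
  dlogits <- matrix(0, nrow(p), ncol(p), dimnames = dimnames(p))
  dloc <- matrix(0, nrow(loc_pred), 4)
  if (parts$normalizer == 0) {
    return(list(loss = multibox_result(0, 0, config, scheme),
                dlogits = dlogits, dloc = dloc))
  }
  w <- scheme_weights(match, batch$census, config$reweight)
  i <- parts$contributing
  onehot <- matrix(0, nrow(p), ncol(p))
  onehot[cbind(seq_len(nrow(p)), parts$true_ix)] <- 1
  if (scheme == "focal") {
    # d/dz of (1-p_t)^g * (-log p_t): via chain rule on p_t
    g <- config$focal_gamma
    pt <- parts$p_true
    dL_dpt <- -(1 - pt)^g / pmax(pt, .LOG_EPS) +
      g * (1 - pt)^(g - 1) * parts$ce
    # dp_t/dz_k = p_t * (1[k=t] - p_k)
    for (ix in i) {
      dlogits[ix, ] <- dL_dpt[ix] * pt[ix] * (onehot[ix, ] - p[ix, ]) / parts$normalizer
    }
    cls <- sum((1 - pt[i])^g * parts$ce[i]) / parts$normalizer
    loc_w <- rep(1, nrow(p))
  } else {
    cls_w <- if (scheme == "none") rep(1, nrow(p)) else w
    dlogits[i, ] <- (cls_w[i] * (p[i, , drop = FALSE] - onehot[i, , drop = FALSE])) /
      parts$normalizer
    cls <- sum((cls_w * parts$ce)[i]) / parts$normalizer
    loc_w <- cls_w
  }
  pos <- parts$pos
  loc <- 0
  if (length(pos) > 0) {
    tgt <- as.matrix(match[pos, c("t_cx", "t_cy", "t_w", "t_h")])
    res <- loc_pred[pos, , drop = FALSE] - tgt
    loc_scale <- if (scheme == "focal") rep(1, length(pos)) else loc_w[pos]
    loc <- sum(loc_scale * rowSums(smooth_l1(res))) / parts$normalizer
    dloc[pos, ] <- config$alpha * loc_scale * smooth_l1_grad(res) / parts$normalizer
  }
  list(loss = multibox_result(cls, loc, config, scheme),
       dlogits = dlogits, dloc = dloc)
}
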