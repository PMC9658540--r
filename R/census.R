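#' Build a class census from per-species instance counts
#'
#' A class census records how many annotated instances each foreground
#' species contributes to a training split. It is the sole input to the
#' loss-reweighting formulas: every weight in [weight_table()] is a
#' function of a species' count and the census total. Background is never
#' a census entry; it receives its weight separately.
#'
#' @param counts A data frame with columns `species` and `count`, or a
#'   named numeric vector (names are species ids, values counts).
#' @return A tibble of class `class_census` with columns `species`
#'   (character) and `count` (integer), carrying the total in
#'   `attr(, "total")`.
#' @examples
#' class_census(c(red_snapper = 120, grouper = 30, triggerfish = 5))
#' @export
class_census <- function(counts) {
  if (is.data.frame(counts)) {
    if (!all(c("species", "count") %in% names(counts))) {
      rlang::abort("`counts` data frame must have columns `species` and `count`.")
    }
    species <- as.character(counts$species)
    n_s <- counts$count
  } else if (is.numeric(counts) && !is.null(names(counts))) {
    species <- names(counts)
    n_s <- unname(counts)
  } else {
    rlang::abort("`counts` must be a data frame or a named numeric vector.")
  }
  if (anyDuplicated(species)) {
    rlang::abort("species ids must be unique.")
  }
  if (any(species == "background")) {
    rlang::abort("background is never a census entry; list foreground species only.")
  }
  if (length(n_s) == 0 || any(!is.finite(n_s)) || any(n_s < 1) || any(n_s != round(n_s))) {
    rlang::abort("every census count must be a positive integer.")
  }
  out <- tibble::tibble(species = species, count = as.integer(n_s))
  attr(out, "total") <- sum(out$count)
  class(out) <- c("class_census", class(out))
  out
}

#' @export
print.class_census <- function(x, ...) {
  cat("<class_census> ", nrow(x), " species, ", census_total(x),
      " instances\n", sep = "")
  NextMethod()
}

#' Total number of foreground instances in a census
#'
#' @param census A [class_census()].
#' @return Integer total (the `n` of the class-aware weight).
#' @export
census_total <- function(census) {
  tot <- attr(census, "total")
  if (is.null(tot)) tot <- sum(census$count)
  as.integer(tot)
}

#' Reweighting configuration for imbalance-aware losses
#'
#' Selects how per-class loss weights are derived from the census.
#' `"class_aware"` uses the multiplying term `(1 - ns/n) / (1 - (ns/n)^eta)`
#' built from each species' instance share; `"class_balanced"` uses
#' `(1 - beta) / (1 - beta^ny)` built from the raw instance count;
#' `"none"` and `"focal"` leave foreground weights at 1 (focal loss acts
#' through the classification term itself, not through class weights).
#'
#' @param scheme One of `"none"`, `"class_aware"`, `"class_balanced"`,
#'   `"focal"`.
#' @param eta Exponent of the class-aware term; default 4. `eta = 1`
#'   collapses every class-aware weight to exactly 1.
#' @param beta Base of the class-balanced term; default 2. Must not be 1.
#' @param background_weight Weight applied to background (negative)
#'   contributions; default 1.
#' @param variant Reading of the class-aware fraction: `"ratio"`
#'   (default), the form mirroring the class-balanced term, or
#'   `"inverse"`, its reciprocal, exposed for sensitivity checks.
#' @param normalize_mean If `TRUE`, rescale foreground weights to mean 1.
#'   Off by default: the raw multiplying term is applied as-is.
#' @return A list of class `reweight_config`.
#' @export
reweight_config <- function(scheme = c("none", "class_aware", "class_balanced", "focal"),
                            eta = 4, beta = 2, background_weight = 1,
                            variant = c("ratio", "inverse"),
                            normalize_mean = FALSE) {
  scheme <- match.arg(scheme)
  variant <- match.arg(variant)
  stopifnot(is.numeric(eta), length(eta) == 1, eta > 0)
  if (!is.numeric(beta) || length(beta) != 1 || beta == 1) {
    rlang::abort("`beta` must be a single numeric value different from 1.")
  }
  stopifnot(is.numeric(background_weight), background_weight > 0)
  structure(
    list(scheme = scheme, eta = eta, beta = beta,
         background_weight = background_weight, variant = variant,
         normalize_mean = isTRUE(normalize_mean)),
    class = "reweight_config"
  )
}

#' Class-aware loss weight from an instance share
#'
#' The multiplying term applied to a species' classification and
#' localization losses: `w = (1 - q) / (1 - q^eta)` with `q = ns/n` the
#' species' share of all training instances. Dominant species (large `q`)
#' are down-weighted toward `1/eta`; rare species keep weights near 1.
#' At `eta = 1` the term is identically 1, recovering the unweighted loss.
#'
#' @param ns Instance count(s) of the species; `1 <= ns < n`.
#' @param n Total foreground instances in the training split.
#' @param eta Positive exponent; default 4.
#' @param variant `"ratio"` (default) or `"inverse"` (the reciprocal
#'   reading of the fraction, for sensitivity analysis).
#' @return Numeric weight(s); in `(1/eta, 1)` for `eta > 1` under the
#'   default variant.
#' @examples
#' class_aware_weight(50, 100, eta = 4)   # 0.5333...
#' class_aware_weight(37, 500, eta = 1)   # exactly 1
#' @export
class_aware_weight <- function(ns, n, eta = 4, variant = c("ratio", "inverse")) {
  variant <- match.arg(variant)
  if (any(!is.finite(ns)) || any(ns < 1) || !is.finite(n) || n < 1) {
    rlang::abort("`ns` and `n` must be positive counts.")
  }
  if (any(ns >= n)) {
    rlang::abort("`ns` must be strictly less than `n`: the weight is undefined (0/0) at ns = n.")
  }
  if (!is.finite(eta) || eta <= 0) rlang::abort("`eta` must be positive.")
  q <- ns / n
  if (eta == 1) return(rep(1, length(q)))
  w <- (1 - q) / (1 - q^eta)
  if (variant == "inverse") w <- 1 / w
  w
}

#' Class-balanced loss weight from an instance count
#'
#' `w = (1 - beta) / (1 - beta^ny)`, evaluated in a numerically stable
#' form for `beta > 1` (equivalently `(beta - 1) / (beta^ny - 1)`).
#' Strictly decreasing in `ny` for `beta > 1`; `w = 1` at `ny = 1` for
#' every valid `beta`. For very large `ny` the weight underflows to 0
#' (with a warning) rather than producing NaN or overflow.
#'
#' @param ny Instance count(s) of the species; `ny >= 1`.
#' @param beta Base; any numeric value other than 1. Default 2.
#' @return Non-negative numeric weight(s).
#' @examples
#' class_balanced_weight(3, beta = 2)    # 1/7
#' class_balanced_weight(10, beta = 2)   # 1/1023
#' @export
class_balanced_weight <- function(ny, beta = 2) {
  if (any(!is.finite(ny)) || any(ny < 1)) rlang::abort("`ny` must be >= 1.")
  if (!is.numeric(beta) || length(beta) != 1 || beta == 1) {
    rlang::abort("`beta` must not equal 1: the weight is undefined (0/0).")
  }
  if (beta > 1) {
    # log-space: log w = log(beta - 1) - [ ny*log(beta) + log1p(-beta^-ny) ]
    log_w <- log(beta - 1) - (ny * log(beta) + log1p(-exp(-ny * log(beta))))
    w <- exp(log_w)
    if (any(w == 0)) {
      rlang::warn("class_balanced_weight underflowed to 0 for very large `ny`.")
    }
    w
  } else {
    (1 - beta) / (1 - beta^ny)
  }
}

#' Per-class weight table for a census under a reweighting scheme
#'
#' Vectorizes the configured weight formula over every species in the
#' census and appends the background entry. Schemes `"none"` and
#' `"focal"` give every foreground species weight 1.
#'
#' @param census A [class_census()] (or a data frame with `species` and
#'   `count` columns).
#' @param config A [reweight_config()].
#' @return A tibble with columns `species`, `count` (NA for background),
#'   `weight`, `scheme`, `eta`, `beta`. Row order follows the census,
#'   background last.
#' @examples
#' cen <- class_census(c(A = 50, B = 50))
#' weight_table(cen, reweight_config("class_aware", eta = 4))
#' @export
weight_table <- function(census, config = reweight_config()) {
  if (!inherits(census, "class_census")) census <- class_census(census)
  stopifnot(inherits(config, "reweight_config"))
  n <- census_total(census)
  w <- switch(
    config$scheme,
    none = ,
    focal = rep(1, nrow(census)),
    class_aware = {
      if (nrow(census) >= 2 && any(census$count >= n)) {
        bad <- census$species[census$count >= n][1]
        rlang::abort(paste0("class-aware weight undefined for species '", bad,
                            "': its count is not below the census total."))
      }
      if (nrow(census) == 1) {
        rlang::abort(paste0("class-aware weight undefined for species '",
                            census$species[1], "': ns = n with a single species."))
      }
      class_aware_weight(census$count, n, config$eta, config$variant)
    },
    class_balanced = class_balanced_weight(census$count, config$beta)
  )
  if (config$normalize_mean && config$scheme %in% c("class_aware", "class_balanced")) {
    w <- w / mean(w)
  }
  tibble::tibble(
    species = c(census$species, "background"),
    count = c(census$count, NA_integer_),
    weight = c(w, config$background_weight),
    scheme = config$scheme,
    eta = config$eta,
    beta = config$beta
  )
}

#' Read a species census from CSV
#'
#' Expects a UTF-8 CSV with header `species,count`, one row per species.
#'
#' @param path Path to the CSV file.
#' @return A [class_census()].
#' @export
read_census_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    species = readr::col_character(),
    count = readr::col_integer()
  ))
  class_census(df)
}

#' Write a species census to CSV
#'
#' @param census A [class_census()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census_csv <- function(census, path) {
  readr::write_csv(tibble::tibble(species = census$species, count = census$count), path)
  invisible(path)
}

#' Write a weight report to CSV
#'
#' Columns `species,count,weight,scheme,eta,beta`, one row per class
#' (background included).
#'
#' @param weights A tibble from [weight_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_report <- function(weights, path) {
  readr::write_csv(weights, path)
  invisible(path)
}
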