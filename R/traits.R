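#' Metabolic mid-weight
#'
#' Mid-test body weight raised to the power 0.75, the standard metabolic
#' scaling used in feed-efficiency models.
#'
#' @param mid_weight Positive mid-test weights (kg).
#' @return `mid_weight^0.75` (kg^0.75).
#' @export
compute_mmw <- function(mid_weight) {
  if (any(!is.finite(mid_weight)) || any(mid_weight <= 0)) {
    stop("mid_weight must be positive and finite")
  }
  mid_weight^0.75
}

#' Derive residual feed intake within feeding groups
#'
#' Fits, separately within each feeding group, the ordinary least-squares
#' regression of average daily feed intake on average daily gain and metabolic
#' mid-weight, and defines RFI as the residual (observed minus expected
#' intake). Negative RFI marks animals eating less than predicted from their
#' growth and maintenance requirements. By construction RFI is phenotypically
#' uncorrelated with ADG and MMW within each group.
#'
#' @param traits Data frame with columns `afi`, `adg`, `feeding_group` and
#'   either `mmw` or `mid_weight` (from which `mmw` is computed).
#' @return The input as a tibble with columns `mmw` and `rfi` added. The
#'   per-group regression coefficients are attached as attribute
#'   `"rfi_models"` and retrievable with [rfi_models()].
#' @export
derive_rfi <- function(traits) {
  traits <- tibble::as_tibble(traits)
  if (!"mmw" %in% names(traits)) {
    if (!"mid_weight" %in% names(traits)) {
      stop("traits must contain mmw or mid_weight")
    }
    traits$mmw <- compute_mmw(traits$mid_weight)
  }
  need <- c("afi", "adg", "mmw", "feeding_group")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop("traits is missing columns: ",
                         paste(miss, collapse = ", "))

  groups <- split(seq_len(nrow(traits)), traits$feeding_group)
  rfi <- rep(NA_real_, nrow(traits))
  models <- vector("list", length(groups))
  for (g in names(groups)) {
    i <- groups[[g]]
    if (length(i) < 3) {
      stop("feeding group ", g, " has fewer than 3 animals (cannot fit ",
           "3-parameter RFI regression)")
    }
    X <- cbind(1, traits$adg[i], traits$mmw[i])
    if (qr(X)$rank < 3) {
      stop("ADG and MMW are collinear within feeding group ", g)
    }
    fit <- stats::lm.fit(X, traits$afi[i])
    rfi[i] <- fit$residuals
    models[[g]] <- tibble::tibble(feeding_group = g,
                                  intercept = unname(fit$coefficients[1]),
                                  b_adg = unname(fit$coefficients[2]),
                                  b_mmw = unname(fit$coefficients[3]),
                                  n_animals = length(i))
  }
  models <- dplyr::bind_rows(models)
  traits$rfi <- rfi
  attr(traits, "rfi_models") <- models
  traits
}

#' Per-group RFI regression coefficients
#' @param x A tibble returned by [derive_rfi()].
#' @return Tibble with one row per feeding group (intercept, ADG and MMW
#'   coefficients, group size).
#' @export
rfi_models <- function(x) {
  m <- attr(x, "rfi_models")
  if (is.null(m)) stop("x carries no RFI models; run derive_rfi() first")
  m
}
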