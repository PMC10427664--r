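## The PERIL composite score: clade volatility (family per-capita extinction
## rate, qhat) plus inverted geographic range (1/ln r) plus inverted thermal
## range (1/T), each min-max rescaled to [0,1] across the analyzed species
## pool, combined into a single intrinsic-vulnerability score.

#' Min-max rescale to [0, 1]
#'
#' @param values numeric vector (NA allowed; at least 2 finite values).
#' @return `(v - min) / (max - min)`. A constant vector rescales to all
#'   zeros with a warning (degenerate spread).
#' @export
rescale01 <- function(values) {
  fin <- is.finite(values)
  if (sum(fin) < 2) stop("rescale01 needs at least 2 finite values")
  lo <- min(values[fin]); hi <- max(values[fin])
  if (hi == lo) {
    warning("constant vector: rescaled to all zeros")
    return(ifelse(fin, 0, NA_real_))
  }
  (values - lo) / (hi - lo)
}

#' Compute PERIL intrinsic-vulnerability scores
#'
#' For each species the three raw components are the family's per-capita
#' Cenozoic extinction rate `qhat`, the inverted geographic range `1/ln(r)`
#' (r in km2, floored at 100 km2 so `ln r > 0`), and the inverted thermal
#' range `1/T` (T in deg C). Ranges are inverted so that larger ranges mean
#' lower vulnerability. Each component is min-max rescaled to [0, 1] across
#' the full analyzed species pool and the score is, by default, the mean of
#' the three scaled components, keeping it in [0, 1]; `combine = "sum"`
#' returns their sum instead (range [0, 3]).
#'
#' Species occupying a single grid cell have `T = 0` and an undefined
#' `1/T`; being maximally thermally restricted, they are assigned the
#' largest finite raw `1/T` observed among `T > 0` species before
#' rescaling, so they map to an `invtr_scaled` of 1 (ties permitting).
#'
#' Species missing any component are skipped with a message and carry `NA`
#' scores; they do not contribute to the rescaling ranges.
#'
#' @param data data.frame with columns `qhat`, `gra_km2`, `tr_c`, and
#'   optionally `species_id`, `family`, `exploited`, `in_fao`, `region`
#'   (carried through for classification and summaries).
#' @param combine `"mean"` (default) or `"sum"`.
#' @return an object of class `"peril"`: a list with `components` (one row
#'   per input row: `qhat_scaled`, `invgr_scaled`, `invtr_scaled`, `peril`),
#'   the input `data`, and the `combine` rule. Methods: `print`, `summary`,
#'   `plot`, [classify()], [vulnerable()].
#' @seealso [classify()], [family_qhat()], [geographic_range_area()],
#'   [thermal_range()]
#' @export
peril <- function(data, combine = c("mean", "sum")) {
  combine <- match.arg(combine)
  data <- as.data.frame(data)
  need <- c("qhat", "gra_km2", "tr_c")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) < 2) stop("need at least 2 species to rescale components")
  if (any(data$gra_km2 < 100, na.rm = TRUE))
    stop("geographic range area below the 100 km2 floor; apply geographic_range_area() first")
  if (any(data$tr_c < 0, na.rm = TRUE)) stop("negative thermal range")
  if (any(data$qhat < 0, na.rm = TRUE)) stop("negative qhat")

  q_raw <- data$qhat
  invgr <- 1 / log(data$gra_km2)
  invtr <- ifelse(data$tr_c > 0, 1 / data$tr_c, NA_real_)
  # single-cell species (T = 0): maximally thermally restricted
  zeroT <- !is.na(data$tr_c) & data$tr_c == 0
  if (any(zeroT)) {
    if (!any(is.finite(invtr))) stop("all species have zero thermal range")
    invtr[zeroT] <- max(invtr[is.finite(invtr)])
  }

  ok <- is.finite(q_raw) & is.finite(invgr) & is.finite(invtr)
  if (!any(ok)) stop("no species with complete PERIL components")
  if (any(!ok))
    message("peril: ", sum(!ok), " species missing a component; skipped")

  sc <- function(v) {
    out <- rep(NA_real_, length(v))
    out[ok] <- rescale01(v[ok])
    out
  }
  comp <- data.frame(qhat_scaled = sc(q_raw), invgr_scaled = sc(invgr),
                     invtr_scaled = sc(invtr))
  total <- comp$qhat_scaled + comp$invgr_scaled + comp$invtr_scaled
  comp$peril <- if (combine == "mean") total / 3 else total
  if ("species_id" %in% names(data)) comp <- cbind(species_id = data$species_id, comp)

  structure(list(components = comp, data = data, combine = combine,
                 call = match.call()),
            class = "peril")
}

#' Extract PERIL scores
#'
#' @param x a `"peril"` object.
#' @return numeric vector of scores (NA for skipped species).
#' @export
peril_scores <- function(x) {
  stopifnot(inherits(x, "peril"))
  x$components$peril
}

#' @export
print.peril <- function(x, ...) {
  s <- peril_scores(x)
  cat("PERIL intrinsic-vulnerability scores\n")
  cat(sprintf("  %d species scored (%d skipped), combine = %s\n",
              sum(!is.na(s)), sum(is.na(s)), x$combine))
  cat(sprintf("  score range: %.3f - %.3f, median %.3f\n",
              min(s, na.rm = TRUE), max(s, na.rm = TRUE),
              median(s, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.peril <- function(object, ...) {
  s <- peril_scores(object)
  out <- list(n = sum(!is.na(s)), combine = object$combine,
              quantiles = quantile(s, c(0, .25, .5, .75, .8, 1), na.rm = TRUE))
  if ("exploited" %in% names(object$data)) {
    ex <- object$data$exploited
    out$by_exploited <- tapply(s, ifelse(ex, "exploited", "non-exploited"),
                               median, na.rm = TRUE)
    ks <- suppressWarnings(ks_two_sample(s[ex & !is.na(s)],
                                         s[!ex & !is.na(s)]))
    out$ks_exploited_vs_not <- ks
  }
  class(out) <- "summary.peril"
  out
}

#' @export
print.summary.peril <- function(x, ...) {
  cat("PERIL score summary (", x$n, " species, combine = ", x$combine,
      ")\n", sep = "")
  print(round(x$quantiles, 3))
  if (!is.null(x$by_exploited)) {
    cat("median by exploitation:\n")
    print(round(x$by_exploited, 3))
    cat(sprintf("KS exploited vs non-exploited: D = %.3f, p = %.3g\n",
                x$ks_exploited_vs_not$statistic, x$ks_exploited_vs_not$p.value))
  }
  invisible(x)
}

#' @export
plot.peril <- function(x, breaks = 30, ...) {
  s <- peril_scores(x)
  ex <- if ("exploited" %in% names(x$data)) x$data$exploited else NULL
  if (is.null(ex)) {
    hist(s, breaks = breaks, main = "PERIL scores", xlab = "PERIL", ...)
  } else {
    h0 <- hist(s[!ex], breaks = breaks, plot = FALSE)
    h1 <- hist(s[ex], breaks = h0$breaks, plot = FALSE)
    plot(h0, col = adjustcolor("grey30", 0.5), freq = FALSE,
         main = "PERIL scores", xlab = "PERIL", ...)
    plot(h1, col = adjustcolor("firebrick", 0.5), freq = FALSE, add = TRUE)
    legend("topright", fill = adjustcolor(c("grey30", "firebrick"), 0.5),
           legend = c("non-exploited", "exploited"), bty = "n")
  }
  invisible(x)
}

#' Classify scores against a global or regional quantile threshold
#'
#' A score is `"above"` when it is strictly greater than the reference
#' pool's quantile (ties fall below); the quantile uses R's default
#' linear-interpolation convention (type 7), recorded in the result's
#' attributes. With `scope = "regional"` each score is compared with the
#' quantile of its own region's reference pool.
#'
#' The reference pool defaults to the scores themselves but can be the full
#' analyzed set when classifying a subset (e.g. FAO-listed species against
#' the global median of all species).
#'
#' @param scores numeric scores to classify, or a `"peril"` object (then
#'   `regions` defaults to `data$region` and the reference is the full
#'   scored set).
#' @param quantile threshold quantile in (0, 1), e.g. 0.5 (median) or 0.8
#'   (top 20%).
#' @param scope `"global"` or `"regional"`.
#' @param regions region label per score (regional scope).
#' @param reference reference pool of scores; defaults to `scores`.
#' @param reference_regions region labels of the reference pool.
#' @param ... unused.
#' @return factor with levels `below`, `above`; attributes `threshold`
#'   (named per region for regional scope), `quantile`, `scope`,
#'   `quantile_type`.
#' @export
classify <- function(scores, ...) UseMethod("classify")

#' @rdname classify
#' @export
classify.peril <- function(scores, quantile = 0.5,
                           scope = c("global", "regional"),
                           regions = NULL, ...) {
  obj <- scores
  if (is.null(regions) && "region" %in% names(obj$data))
    regions <- obj$data$region
  classify.default(peril_scores(obj), quantile = quantile, scope = scope,
                   regions = regions, ...)
}

#' @rdname classify
#' @export
classify.default <- function(scores, quantile = 0.5,
                             scope = c("global", "regional"),
                             regions = NULL, reference = scores,
                             reference_regions = regions, ...) {
  scope <- match.arg(scope)
  stopifnot(quantile > 0, quantile < 1)
  if (scope == "global") {
    thr <- stats::quantile(reference, quantile, na.rm = TRUE, type = 7)
    lab <- ifelse(scores > thr, "above", "below")
  } else {
    if (is.null(regions) || is.null(reference_regions))
      stop("regional scope requires region labels")
    pools <- split(reference, reference_regions)
    small <- names(pools)[vapply(pools, function(p) sum(!is.na(p)) < 5, logical(1))]
    if (length(small))
      warning("region(s) with < 5 species: ", paste(small, collapse = ", "))
    thr <- vapply(pools, stats::quantile, numeric(1), probs = quantile,
                  na.rm = TRUE, type = 7)
    lab <- ifelse(scores > thr[as.character(regions)], "above", "below")
  }
  structure(factor(lab, levels = c("below", "above")),
            threshold = thr, quantile = quantile, scope = scope,
            quantile_type = 7L)
}

#' Logical vulnerability flag per species
#'
#' Convenience wrapper around [classify()]: `TRUE` where the species' score
#' is strictly above the threshold.
#'
#' @inheritParams classify.default
#' @return logical vector (NA where the score is NA).
#' @export
vulnerable <- function(scores, quantile = 0.5, scope = "global",
                       regions = NULL, reference = scores,
                       reference_regions = regions) {
  lab <- classify.default(scores, quantile = quantile, scope = scope,
                          regions = regions, reference = reference,
                          reference_regions = reference_regions)
  as.character(lab) == "above"
}
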