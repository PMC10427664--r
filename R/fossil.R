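## Clade volatility: per-capita genus extinction rates of families estimated
## from first/last stratigraphic occurrences by boundary-crosser counts.
## For an interval of duration dt with Nb genera crossing its bottom boundary
## and Nbt of them also crossing its top boundary, the per-capita rate is
## q = -ln(Nbt/Nb) / dt. Singletons (genera confined to one stage) cross no
## boundary and enter neither count.

#' Construct and validate a stage scale
#'
#' @param name stage names, ordered old to young.
#' @param base_age age of the stage bottom (Ma).
#' @param top_age age of the stage top (Ma).
#' @return data.frame `name, base_age, top_age, dt` (class `stage_scale`).
#'   Stages must be contiguous (`top_age[i] == base_age[i+1]`) with strictly
#'   positive durations.
#' @export
stage_scale <- function(name, base_age, top_age) {
  stopifnot(length(name) == length(base_age), length(name) == length(top_age))
  dt <- base_age - top_age
  if (any(dt <= 0)) stop("stage durations must be positive")
  if (length(name) > 1 && any(abs(top_age[-length(name)] - base_age[-1]) > 1e-9))
    stop("stages must be contiguous (top of one = base of the next)")
  if (anyDuplicated(name)) stop("duplicate stage names")
  out <- data.frame(name = as.character(name), base_age = base_age,
                    top_age = top_age, dt = dt, stringsAsFactors = FALSE)
  class(out) <- c("stage_scale", "data.frame")
  out
}

#' The Cenozoic stage scale
#'
#' Standard Cenozoic stages (Danian through Holocene) with ICS boundary ages
#' in Ma, packaged as the default timescale for [family_qhat()]. Any
#' contiguous [stage_scale()] is accepted in its place.
#'
#' @return a `stage_scale` of 22 stages spanning 66-0 Ma.
#' @export
cenozoic_stages <- function() {
  stage_scale(
    name = c("Danian", "Selandian", "Thanetian", "Ypresian", "Lutetian",
             "Bartonian", "Priabonian", "Rupelian", "Chattian", "Aquitanian",
             "Burdigalian", "Langhian", "Serravallian", "Tortonian",
             "Messinian", "Zanclean", "Piacenzian", "Gelasian", "Calabrian",
             "Chibanian", "Late Pleistocene", "Holocene"),
    base_age = c(66, 61.6, 59.2, 56, 47.8, 41.2, 37.71, 33.9, 27.82, 23.03,
                 20.44, 15.97, 13.82, 11.63, 7.246, 5.333, 3.6, 2.58, 1.8,
                 0.774, 0.129, 0.0117),
    top_age = c(61.6, 59.2, 56, 47.8, 41.2, 37.71, 33.9, 27.82, 23.03, 20.44,
                15.97, 13.82, 11.63, 7.246, 5.333, 3.6, 2.58, 1.8, 0.774,
                0.129, 0.0117, 0))
}

.validate_ranges <- function(ranges, scale) {
  f <- match(ranges$first_stage, scale$name)
  l <- match(ranges$last_stage, scale$name)
  if (anyNA(f) || anyNA(l))
    stop("stage name(s) not in scale: ",
         paste(unique(c(ranges$first_stage[is.na(f)],
                        ranges$last_stage[is.na(l)])), collapse = ", "))
  if (any(f > l))
    stop("first_stage younger than last_stage for genus: ",
         paste(ranges$genus[f > l], collapse = ", "))
  invisible(cbind(first = f, last = l))
}

#' Boundary-crosser counts for one stage
#'
#' `Nb` counts genera whose first occurrence is strictly older than the
#' stage and whose range reaches the stage or beyond (they cross the stage's
#' bottom boundary); `Nbt` counts the subset whose last occurrence is
#' strictly younger (they also cross the top boundary).
#'
#' @param ranges data.frame `genus, family, first_stage, last_stage`.
#' @param stage stage name.
#' @param scale a [stage_scale()].
#' @return list with `stage`, `Nb`, `Nbt`, `dt`.
#' @export
boundary_crossers <- function(ranges, stage, scale) {
  i <- match(stage, scale$name)
  if (is.na(i)) stop("stage not in scale: ", stage)
  idx <- .validate_ranges(ranges, scale)
  nb <- idx[, "first"] < i & idx[, "last"] >= i
  nbt <- nb & idx[, "last"] > i
  list(stage = stage, Nb = sum(nb), Nbt = sum(nbt), dt = scale$dt[i])
}

#' Per-capita extinction rate for one interval
#'
#' @param Nb genera crossing the bottom boundary.
#' @param Nbt genera crossing both boundaries.
#' @param dt interval duration, Myr.
#' @return `q = -ln(Nbt/Nb)/dt` per Myr; 0 when `Nbt == Nb`; `Inf` (complete
#'   extinction, undefined rate — dropped by [family_qhat()]) when
#'   `Nbt == 0`.
#' @export
interval_extinction_rate <- function(Nb, Nbt, dt) {
  stopifnot(Nb > 0, Nbt >= 0, Nbt <= Nb, dt > 0)
  if (Nbt == 0) return(Inf)
  -log(Nbt / Nb) / dt
}

#' Family-level per-capita extinction rate through a timescale
#'
#' Estimates a family's clade volatility: boundary-crosser counts are formed
#' per stage from the family's genus ranges and per-stage rates are combined
#' across the timescale. The default aggregation is the duration-weighted
#' mean of defined per-stage rates, `sum(q_i * dt_i) / sum(dt_i)` over
#' stages with `Nb > 0` and `Nbt > 0` — algebraically this pools the stage
#' survivorships, `sum(ln(Nb_i/Nbt_i)) / sum(dt_i)`, over those stages.
#' `method = "mean"` instead averages the per-stage rates unweighted, which
#' upweights short stages. Stages with complete extinction (`Nbt = 0`) have
#' no finite rate and are dropped with a message.
#'
#' @param ranges data.frame `genus, family, first_stage, last_stage`.
#' @param scale a [stage_scale()]; defaults to [cenozoic_stages()].
#' @param family family name, or `NULL` to use all genera in `ranges`.
#' @param method `"weighted"` (default) or `"mean"`.
#' @return rate per Myr, with attributes `n_genera` and `n_intervals`;
#'   `NA` (with a message) if no stage yields a usable count.
#' @export
family_qhat <- function(ranges, scale = cenozoic_stages(), family = NULL,
                        method = c("weighted", "mean")) {
  method <- match.arg(method)
  if (!is.null(family)) ranges <- ranges[ranges$family == family, , drop = FALSE]
  if (!nrow(ranges)) {
    message("family_qhat: no genera for family ", family)
    return(NA_real_)
  }
  idx <- .validate_ranges(ranges, scale)
  ns <- nrow(scale)
  Nb <- Nbt <- integer(ns)
  for (i in seq_len(ns)) {
    nb <- idx[, "first"] < i & idx[, "last"] >= i
    Nb[i] <- sum(nb)
    Nbt[i] <- sum(nb & idx[, "last"] > i)
  }
  usable <- Nb > 0 & Nbt > 0
  dropped <- Nb > 0 & Nbt == 0
  if (any(dropped))
    message("family_qhat: ", sum(dropped),
            " interval(s) with complete extinction dropped (rate undefined)")
  if (!any(usable)) {
    message("family_qhat: no usable intervals")
    out <- NA_real_
  } else {
    q <- -log(Nbt[usable] / Nb[usable]) / scale$dt[usable]
    out <- if (method == "weighted")
      sum(q * scale$dt[usable]) / sum(scale$dt[usable])
    else mean(q)
  }
  attr(out, "n_genera") <- length(unique(ranges$genus))
  attr(out, "n_intervals") <- sum(usable)
  out
}

#' Per-family extinction-rate table
#'
#' @param ranges data.frame of genus ranges for several families.
#' @param scale a [stage_scale()].
#' @param method passed to [family_qhat()].
#' @return data.frame `family, qhat, n_genera, n_intervals`.
#' @export
family_qhat_table <- function(ranges, scale = cenozoic_stages(),
                              method = c("weighted", "mean")) {
  method <- match.arg(method)
  fams <- sort(unique(ranges$family))
  rows <- lapply(fams, function(f) {
    q <- suppressMessages(family_qhat(ranges, scale, family = f, method = method))
    data.frame(family = f, qhat = as.numeric(q),
               n_genera = attr(q, "n_genera") %||% 0L,
               n_intervals = attr(q, "n_intervals") %||% 0L)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
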