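# Likert rescaling and the composite conspiracism index.

#' Describe a Likert trait scale
#'
#' @param name Scale name (e.g. `"CMS"`, `"GCB"`).
#' @param n_items Number of items.
#' @param likert_min,likert_max Theoretical response bounds of the scale.
#' @param reverse_items Integer indices of reverse-keyed items.
#' @param subscales Optional named list of item-index vectors (e.g. CMS
#'   skepticism/ideation; GCB facets). Item-to-subscale maps are supplied by
#'   the user.
#' @return An object of class `scale_spec`.
#' @export
scale_spec <- function(name, n_items, likert_min, likert_max,
                       reverse_items = integer(0), subscales = list()) {
  stopifnot(likert_min < likert_max, n_items >= 1L)
  if (length(reverse_items) &&
      !all(reverse_items %in% seq_len(n_items))) {
    stop("reverse_items outside 1..n_items")
  }
  for (s in subscales) {
    if (!all(s %in% seq_len(n_items))) stop("subscale item outside 1..n_items")
  }
  structure(list(name = name, n_items = as.integer(n_items),
                 likert_min = likert_min, likert_max = likert_max,
                 reverse_items = as.integer(reverse_items),
                 subscales = subscales),
            class = "scale_spec")
}

#' Rescale Likert responses to the common 0-1 range
#'
#' `z = (x - min(L)) / (max(L) - min(L))`, where `min(L)` and `max(L)` are
#' the theoretical bounds of the scale, so 0 is *strongly disagree*, 1 is
#' *strongly agree*, and the midpoint of an odd scale maps to 0.50.
#' Reverse-keyed items are mapped to `1 - z`.
#'
#' @param x Integer vector of raw responses (`NA` allowed, passed through).
#' @param spec A `scale_spec`.
#' @param items Optional integer vector (same length as `x`) of item indices,
#'   used for reverse keying and error messages; defaults to `1..length(x)`.
#' @param pid Optional participant id for error messages.
#' @return Numeric vector of rescaled responses in `[0, 1]`.
#' @export
rescale_likert <- function(x, spec, items = seq_along(x), pid = NULL) {
  stopifnot(inherits(spec, "scale_spec"), length(items) == length(x))
  bad <- !is.na(x) & (x < spec$likert_min | x > spec$likert_max)
  if (any(bad)) {
    stop(sprintf("response out of range [%s, %s] on scale '%s'%s (item %s: value %s)",
                 spec$likert_min, spec$likert_max, spec$name,
                 if (is.null(pid)) "" else paste0(" for participant ", pid),
                 items[which(bad)[1]], x[which(bad)[1]]))
  }
  z <- (x - spec$likert_min) / (spec$likert_max - spec$likert_min)
  rev <- items %in% spec$reverse_items
  z[rev] <- 1 - z[rev]
  z
}

#' Composite conspiracism score of one participant
#'
#' Mean of the rescaled item responses. With `missing = "available"`
#' (default) missing items are excluded and their count attached as the
#' `n_missing` attribute; with `missing = "strict"` any missing item yields
#' `NA`.
#'
#' @param responses Integer vector of raw responses, one per item (length
#'   `spec$n_items`; `NA` for unanswered items).
#' @param spec A `scale_spec`.
#' @param missing Missing-item policy.
#' @param pid Optional participant id for error messages.
#' @return Composite score in `[0, 1]`, or `NA` when nothing is scorable.
#' @export
composite_conspiracism <- function(responses, spec,
                                   missing = c("available", "strict"),
                                   pid = NULL) {
  missing <- match.arg(missing)
  stopifnot(inherits(spec, "scale_spec"))
  if (length(responses) != spec$n_items) {
    stop(sprintf("expected %d responses on scale '%s', got %d",
                 spec$n_items, spec$name, length(responses)))
  }
  z <- rescale_likert(responses, spec, items = seq_len(spec$n_items),
                      pid = pid)
  n_miss <- sum(is.na(z))
  if (n_miss == length(z)) return(NA_real_)
  if (missing == "strict" && n_miss > 0L) return(NA_real_)
  structure(mean(z, na.rm = TRUE), n_missing = n_miss)
}

#' Subscale scores of one participant
#' @inheritParams composite_conspiracism
#' @return Named numeric vector, one available-item mean per subscale.
#' @export
subscale_scores <- function(responses, spec, pid = NULL) {
  z <- rescale_likert(responses, spec, items = seq_len(spec$n_items),
                      pid = pid)
  vapply(spec$subscales, function(idx) {
    v <- z[idx]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
}
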