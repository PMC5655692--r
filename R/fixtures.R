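fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "triaxwall")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)  # pre-install use
  if (!file.exists(p)) stop("fixture not found: ", file, call. = FALSE)
  p
}

#' Packaged material-constant tables
#'
#' Returns the published per-subject material constants (with their reported
#' per-component goodness-of-fit values) for the entire vessel wall or the
#' intima-media (IM) layer, as a data.frame.
#'
#' @param table `"wall"` or `"IM"`.
#' @param which `"passive"` or `"active"`.
#' @return data.frame with one row per subject.
#' @export
constant_table <- function(table = c("wall", "IM"),
                           which = c("passive", "active")) {
  table <- match.arg(table)
  which <- match.arg(which)
  file <- sprintf("%s_%s_constants.csv",
                  if (table == "wall") "wall" else "im", which)
  utils::read.csv(fixture_path(file), check.names = FALSE)
}

#' Look up packaged material constants
#'
#' Retrieves published constant sets as constructed objects. For
#' `table = "wall"` or `"IM"`, `subject` names a heart (e.g. `"Heart 1"`)
#' and a list with `$passive` and `$active` constants is returned. For
#' `table = "two_layer"` the pooled active IM constants used by the two-layer
#' wall model are returned. For `table = "fig4"`, `subject = "3d"` gives the
#' pooled-wall active constants of the sensitivity analysis and
#' `subject = "2d"` the planar comparison law; for these two the stress scale
#' and offset are package defaults (only the stretch-scale constants were
#' published), which affects curve amplitude but none of the sensitivity
#' conclusions.
#'
#' @param table One of `"wall"`, `"IM"`, `"two_layer"`, `"fig4"`.
#' @param subject Subject key; see Details.
#' @return Constants object(s); see Description.
#' @export
#' @examples
#' published_constants("two_layer")$C2   # 28.92
published_constants <- function(table = c("wall", "IM", "two_layer", "fig4"),
                            subject = NULL) {
  table <- match.arg(table)
  if (table %in% c("wall", "IM")) {
    pas <- constant_table(table, "passive")
    act <- constant_table(table, "active")
    if (is.null(subject) || !subject %in% pas$subject_id) {
      stop("unknown subject; valid keys: ",
           paste(pas$subject_id, collapse = ", "), call. = FALSE)
    }
    p <- pas[pas$subject_id == subject, ]
    a <- act[act$subject_id == subject, ]
    return(list(
      passive = passive_constants(p$C1, p$a1, p$a2, p$a3, p$a4, p$a5, p$a6,
                                  subject_id = subject, layer = p$layer),
      active = active_constants(a$C2, a$b1, a$b2, a$b3, a$b_prime,
                                subject_id = subject, layer = a$layer)
    ))
  }
  sp <- utils::read.csv(fixture_path("special_active_constants.csv"),
                        check.names = FALSE)
  key <- switch(table,
    two_layer = "two_layer_IM",
    fig4 = {
      if (is.null(subject)) subject <- "3d"
      if (!subject %in% c("3d", "2d")) {
        stop("unknown subject; valid keys: 3d, 2d", call. = FALSE)
      }
      if (subject == "3d") "fig4_wall" else "fig4_2d"
    })
  row <- sp[sp$key == key, ]
  if (is.na(row$b3)) {
    active_constants_2d(row$C2, row$b1, row$b2, row$b_prime, layer = key)
  } else {
    active_constants(row$C2, row$b1, row$b2, row$b3, row$b_prime, layer = key)
  }
}

#' Mean constants of a published table
#'
#' Convenience constructor: column means of the per-subject rows.
#'
#' @inheritParams constant_table
#' @return List with `$passive` and `$active` constants built from the
#'   column means.
#' @export
mean_constants <- function(table = c("wall", "IM")) {
  table <- match.arg(table)
  pas <- constant_table(table, "passive")
  act <- constant_table(table, "active")
  list(
    passive = passive_constants(
      mean(pas$C1), mean(pas$a1), mean(pas$a2), mean(pas$a3),
      mean(pas$a4), mean(pas$a5), mean(pas$a6),
      subject_id = "mean", layer = table),
    active = active_constants(
      mean(act$C2), mean(act$b1), mean(act$b2), mean(act$b3),
      mean(act$b_prime), subject_id = "mean", layer = table)
  )
}

#' Summary statistic of a packaged constant column
#'
#' Arithmetic mean or sample standard deviation (n - 1 denominator) across
#' subjects, optionally rounded to a given number of decimal digits for
#' comparison with printed summary rows.
#'
#' @inheritParams constant_table
#' @param column Column name, e.g. `"C1"`, `"b3"`, `"R2_theta"`.
#' @param statistic `"mean"` or `"sd"`.
#' @param digits If non-`NULL`, round the result to this many decimals.
#' @return Scalar.
#' @export
column_stats <- function(table, which, column, statistic = c("mean", "sd"),
                         digits = NULL) {
  statistic <- match.arg(statistic)
  df <- constant_table(table, which)
  if (!column %in% names(df)) {
    stop("unknown column: ", column, call. = FALSE)
  }
  x <- df[[column]]
  out <- if (statistic == "mean") mean(x) else stats::sd(x)
  if (!is.null(digits)) out <- round(out, digits)
  out
}
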