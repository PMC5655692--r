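#' Reduce one inflation-extension record to mean-wall 1st PK stresses
#'
#' Converts a (pressure, outer diameter, axial force) observation into the
#' experimental mean-wall first Piola-Kirchhoff stress triple:
#' \deqn{T_\theta = P r_i / (\lambda_\theta h), \quad
#'       T_z = \frac{1}{\lambda_z}\left[\frac{F}{\pi(r_o^2-r_i^2)} +
#'             \frac{P r_i^2}{h (r_o + r_i)}\right], \quad
#'       T_r = \frac{-r_i P}{(r_o + r_i)\lambda_r}}
#' with the loaded inner radius from wall-volume conservation, the mean-wall
#' circumferential stretch at the mid-wall radius, and the radial stretch
#' from incompressibility. Pressure is converted from mmHg to kPa before
#' use; with diameters in mm and forces in mN all stresses are in kPa.
#'
#' @param P_mmHg Transmural pressure (mmHg), non-negative.
#' @param d_o_mm Loaded outer diameter (mm).
#' @param F_mN Axial force (mN).
#' @param lam_z Axial stretch ratio.
#' @param A0 No-load wall cross-sectional area (mm^2).
#' @param l0 Zero-stress mid-wall circumferential length (mm).
#' @return data.frame with `lam_theta`, `T_theta`, `T_z`, `T_r` (kPa);
#'   vectorized over the record arguments.
#' @export
reduce_record <- function(P_mmHg, d_o_mm, F_mN, lam_z, A0, l0) {
  if (any(P_mmHg < 0)) stop("pressure must be non-negative", call. = FALSE)
  if (any(d_o_mm <= 0)) stop("outer diameter must be positive", call. = FALSE)
  r_o <- d_o_mm / 2
  r_i <- loaded_inner_radius(r_o, A0, lam_z)
  h <- r_o - r_i
  lam_theta <- pi * (r_i + r_o) / l0
  lam_r <- radial_stretch(lam_theta, lam_z)
  P <- mmHg_to_kPa(P_mmHg)
  data.frame(
    lam_theta = lam_theta,
    T_theta = P * r_i / (lam_theta * h),
    T_z = (1 / lam_z) * (F_mN / (pi * (r_o^2 - r_i^2)) +
                           P * r_i^2 / (h * (r_o + r_i))),
    T_r = -r_i * P / ((r_o + r_i) * lam_r)
  )
}

measurement_columns <- c("subject_id", "layer", "state", "lam_z",
                         "P_mmHg", "d_o_mm", "F_mN")

#' Reduce a measurement table to experimental stress points
#'
#' Applies [reduce_record()] row-wise to an inflation-extension measurement
#' table and returns one stress point per record, keyed by activation state
#' and axial stretch, ordered by (`state`, `lam_z`, `P_mmHg`) with the
#' original ordering retained within ties. Passive and total (activated)
#' groups are never merged. Duplicated records yield duplicated points.
#'
#' @param records data.frame with columns `subject_id`, `layer`, `state`
#'   (`"passive"` or `"total"`), `lam_z`, `P_mmHg`, `d_o_mm`, `F_mN`.
#' @param A0 No-load wall cross-sectional area (mm^2).
#' @param l0 Zero-stress mid-wall circumferential length (mm).
#' @return data.frame: the input keys plus `lam_theta`, `T_theta`, `T_z`,
#'   `T_r` (kPa).
#' @export
reduce_dataset <- function(records, A0, l0) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(measurement_columns, names(records))
  if (length(missing_cols)) {
    stop("missing measurement columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- c("lam_z", "P_mmHg", "d_o_mm", "F_mN")
  for (cn in num) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(records[[cn]]))))
    if (length(bad)) {
      stop("non-numeric or missing ", cn, " at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (!all(records$state %in% c("passive", "total"))) {
    bad <- which(!records$state %in% c("passive", "total"))
    stop("unknown activation state at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  red <- reduce_record(records$P_mmHg, records$d_o_mm, records$F_mN,
                       records$lam_z, A0, l0)
  out <- cbind(records[measurement_columns], red)
  out[order(out$state, out$lam_z, out$P_mmHg), , drop = FALSE]
}

#' Read / write inflation-extension measurement CSVs
#'
#' Plain comma-separated files with a header row holding the exact column
#' names `subject_id, layer, state, lam_z, P_mmHg, d_o_mm, F_mN`.
#'
#' @param path File path.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(measurement_columns, names(df))
  if (length(missing_cols)) {
    stop("measurement file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_measurements
#' @param records Measurement data.frame.
#' @export
write_measurements <- function(records, path) {
  utils::write.csv(records[measurement_columns], path, row.names = FALSE)
}
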