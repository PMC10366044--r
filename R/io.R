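#' Write trajectory totals to CSV
#'
#' Full-precision (17 significant digits) CSV so that a read-back reproduces
#' the totals bit-for-bit. Units are carried in the column headers.
#'
#' @param traj A [run_simulation()] trajectory (anything with a `totals`
#'   data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_totals_csv <- function(traj, path) {
  tt <- traj$totals
  hdr <- c("t [s]", "N_R_free [molecules]", "N_C [molecules]",
           "N_L_free [molecules]", "N_L_available [molecules]",
           "contact_area [um^2]")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = ","), con)
  for (i in seq_len(nrow(tt))) {
    writeLines(paste(sprintf("%.17g", as.numeric(tt[i, ])), collapse = ","),
               con)
  }
  invisible(path)
}

#' Read back a totals CSV
#'
#' @param path File written by [write_totals_csv()].
#' @return Data frame with the original column names.
#' @export
read_totals_csv <- function(path) {
  out <- read.csv(path, check.names = FALSE, colClasses = "numeric")
  names(out) <- c("t", "N_R_free", "N_C", "N_L_free", "N_L_available",
                  "contact_area")
  out
}

#' Write a legacy-VTK snapshot of the meridian
#'
#' One polyline through the current node positions (meridian in the
#' rho-y plane), with the nodal fields as point data — loadable in ParaView
#' for quick inspection of the coffee ring and gap profile.
#'
#' @param state A `"field_state"`.
#' @param frame The matching kinematics frame.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_snapshot <- function(state, frame, path) {
  n <- length(frame$rho)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("membrane meridian at t = %g s", state$t),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.10g %.10g 0", frame$rho, frame$y), con)
  writeLines(sprintf("LINES 1 %d", n + 1L), con)
  writeLines(paste(c(n, seq_len(n) - 1L), collapse = " "), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  fields <- list(c_R_free = state_free(state), c_L = state$c_L,
                 c_C = state_complex(state), S_L = state$S_L,
                 g_N = frame$g_N, lambda_a = frame$lambda_a)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default",
                 sprintf("%.10g", fields[[nm]])), con)
  }
  invisible(path)
}

#' Write the shape schedule to CSV
#'
#' @param traj A [run_simulation()] trajectory.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frames_csv <- function(traj, path) {
  fr <- traj$frames
  hdr <- c("t [s]", "a [um]", "h [um]", "R_s [um]", "area [um^2]",
           "lambda_a [-]")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = ","), con)
  for (i in seq_len(nrow(fr))) {
    writeLines(paste(sprintf("%.17g", as.numeric(fr[i, ])), collapse = ","),
               con)
  }
  invisible(path)
}
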