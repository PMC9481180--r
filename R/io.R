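#' Write a sweep set to disk
#'
#' Two dialects are supported:
#' \describe{
#'   \item{csv}{Long-format UTF-8 CSV with header
#'     `sweep_id,time_s,voltage_mV,current_pA` (one row per sample), plus a
#'     JSON sidecar `<path>.json` carrying the protocol, cell id, and
#'     access-resistance series. Numbers are written with 17 significant
#'     digits so the round trip is exact.}
#'   \item{hdf5}{One group per sweep with a float64 `voltage_mV` dataset and
#'     `current_pA` / `t0_s` attributes; protocol fields and cell metadata as
#'     file-level attributes.}
#' }
#'
#' @param s A [sweep_set()].
#' @param path Output path.
#' @param format `"csv"` or `"hdf5"`.
#' @return Invisibly, `path`.
#' @seealso [read_sweepset()]
#' @export
write_sweepset <- function(s, path, format = c("csv", "hdf5")) {
  stopifnot(inherits(s, "sweep_set"))
  format <- match.arg(format)
  if (length(s$sweeps) == 0) stop("refusing to serialize an empty sweep set")
  if (format == "csv") write_sweepset_csv(s, path) else write_sweepset_h5(s, path)
  invisible(path)
}

#' Read a sweep set from disk
#'
#' @param path Path written by [write_sweepset()] (for CSV, the `<path>.json`
#'   sidecar must sit next to it).
#' @param format `"csv"` or `"hdf5"`.
#' @return A [sweep_set()].
#' @export
read_sweepset <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "csv") read_sweepset_csv(path) else read_sweepset_h5(path)
}

fmt17 <- function(x) sprintf("%.17g", x)

protocol_to_list <- function(p) {
  list(holding_potential = p$holding_potential, step_onset = p$step_onset,
       step_duration = p$step_duration, step_amplitudes = p$step_amplitudes,
       increment = p$increment, sample_rate = p$sample_rate, held = p$held)
}

protocol_from_list <- function(l) {
  step_protocol(
    step_amplitudes = as.numeric(unlist(l$step_amplitudes)),
    holding_potential = l$holding_potential, step_onset = l$step_onset,
    step_duration = l$step_duration, increment = l$increment,
    sample_rate = l$sample_rate, held = isTRUE(l$held)
  )
}

write_sweepset_csv <- function(s, path) {
  p <- s$protocol
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("sweep_id,time_s,voltage_mV,current_pA", con)
  for (sw in s$sweeps) {
    tt <- sweep_times(sw, p)
    writeLines(paste(sw$sweep_id, fmt17(tt), fmt17(sw$voltage),
                     fmt17(sw$injected_current), sep = ","), con)
  }
  side <- list(
    cell_id = s$cell_id,
    protocol = protocol_to_list(p),
    access_resistance = s$access_resistance,
    t0 = vapply(s$sweeps, `[[`, numeric(1), "t0")
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

read_sweepset_csv <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                         colClasses = c(sweep_id = "character"))
  need <- c("sweep_id", "time_s", "voltage_mV", "current_pA")
  missing <- setdiff(need, names(dat))
  if (length(missing)) {
    stop("sweep CSV ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "),
         " (units are encoded in the column names; no guessing)")
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("protocol sidecar missing: ", sidecar,
         " (CSV dialect stores the step protocol in a JSON sidecar)")
  }
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  protocol <- protocol_from_list(side$protocol)
  ids <- unique(dat$sweep_id)
  t0s <- as.numeric(unlist(side$t0))
  if (length(t0s) != length(ids)) t0s <- rep(0, length(ids))
  sweeps <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- dat[dat$sweep_id == ids[i], ]
    cur <- unique(rows$current_pA)
    if (length(cur) != 1) {
      stop("sweep record '", ids[i], "' in ", path,
           " has non-constant current_pA")
    }
    if (anyNA(rows$voltage_mV)) {
      stop("sweep record '", ids[i], "' in ", path, " has missing voltage samples")
    }
    sweeps[[i]] <- sweep(ids[i], rows$voltage_mV, cur, t0 = t0s[i])
  }
  ra <- side$access_resistance
  if (!is.null(ra)) ra <- as.numeric(unlist(ra))
  sweep_set(side$cell_id, protocol, sweeps, access_resistance = ra)
}

write_sweepset_h5 <- function(s, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  fid <- rhdf5::H5Fopen(path)
  p <- s$protocol
  rhdf5::h5writeAttribute(s$cell_id, fid, "cell_id")
  rhdf5::h5writeAttribute(p$holding_potential, fid, "holding_potential_mV")
  rhdf5::h5writeAttribute(p$step_onset, fid, "step_onset_s")
  rhdf5::h5writeAttribute(p$step_duration, fid, "step_duration_s")
  rhdf5::h5writeAttribute(p$step_amplitudes, fid, "step_amplitudes_pA")
  rhdf5::h5writeAttribute(p$increment, fid, "increment_pA")
  rhdf5::h5writeAttribute(p$sample_rate, fid, "sample_rate_Hz")
  rhdf5::h5writeAttribute(as.integer(p$held), fid, "held")
  if (!is.null(s$access_resistance)) {
    rhdf5::h5writeAttribute(s$access_resistance, fid, "access_resistance_Mohm")
  }
  rhdf5::h5writeAttribute(vapply(s$sweeps, `[[`, character(1), "sweep_id"),
                          fid, "sweep_order")
  for (sw in s$sweeps) {
    grp <- paste0("sweep_", sw$sweep_id)
    rhdf5::h5createGroup(fid, grp)
    rhdf5::h5write(sw$voltage, fid, paste0(grp, "/voltage_mV"))
    gid <- rhdf5::H5Gopen(fid, grp)
    rhdf5::h5writeAttribute(sw$injected_current, gid, "current_pA")
    rhdf5::h5writeAttribute(sw$t0, gid, "t0_s")
    rhdf5::H5Gclose(gid)
  }
  rhdf5::H5Fclose(fid)
}

h5attr1 <- function(attrs, name, path) {
  if (is.null(attrs[[name]])) {
    stop("HDF5 sweep file ", path, " lacks required attribute '", name, "'")
  }
  attrs[[name]]
}

read_sweepset_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  attrs <- rhdf5::h5readAttributes(path, "/")
  protocol <- step_protocol(
    step_amplitudes = as.numeric(h5attr1(attrs, "step_amplitudes_pA", path)),
    holding_potential = as.numeric(h5attr1(attrs, "holding_potential_mV", path)),
    step_onset = as.numeric(h5attr1(attrs, "step_onset_s", path)),
    step_duration = as.numeric(h5attr1(attrs, "step_duration_s", path)),
    increment = as.numeric(h5attr1(attrs, "increment_pA", path)),
    sample_rate = as.numeric(h5attr1(attrs, "sample_rate_Hz", path)),
    held = as.integer(h5attr1(attrs, "held", path)) == 1L
  )
  ids <- as.character(h5attr1(attrs, "sweep_order", path))
  sweeps <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    grp <- paste0("sweep_", ids[i])
    v <- as.numeric(rhdf5::h5read(path, paste0(grp, "/voltage_mV")))
    ga <- rhdf5::h5readAttributes(path, grp)
    sweeps[[i]] <- sweep(ids[i], v,
                         as.numeric(h5attr1(ga, "current_pA", path)),
                         t0 = as.numeric(h5attr1(ga, "t0_s", path)))
  }
  ra <- attrs[["access_resistance_Mohm"]]
  sweep_set(as.character(h5attr1(attrs, "cell_id", path)), protocol, sweeps,
            access_resistance = if (is.null(ra)) NULL else as.numeric(ra))
}
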