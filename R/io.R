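#' Write / read BOLD volumes as NIfTI-1
#'
#' The repetition time is stored in (and required from) the 4th pixdim
#' slot of the header; the voxel-to-mm affine goes into the sform.
#'
#' @param bold a [bold_series()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `write_bold` returns `path` invisibly; `read_bold` returns a
#'   [bold_series()].
#' @export
write_bold <- function(bold, path) {
  stopifnot(inherits(bold, "bold_series"))
  img <- RNifti::asNifti(bold$data)
  img <- RNifti::`sform<-`(img, structure(bold$affine, code = 2L))
  pd <- RNifti::pixdim(img)  # spatial spacings now derive from the sform
  pd[4] <- bold$tr
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) {
    stop("expected a 4-D NIfTI volume, got ", length(d), " dimensions")
  }
  # the raw header, not the sanitised image attributes: a zero pixdim[4]
  # must surface as a missing TR, not be silently repaired to 1
  tr <- RNifti::niftiHeader(path)$pixdim[5]
  if (!is.finite(tr) || tr <= 0) {
    stop("NIfTI header carries no repetition time (pixdim[4] = ",
         tr, "); refusing to guess")
  }
  aff <- structure(RNifti::xform(img), dimnames = NULL)
  data <- array(as.numeric(img), dim = d)
  if (!all(is.finite(data))) stop("non-finite values in BOLD file")
  bold_series(data, tr = tr, affine = aff)
}

#' Write / read EEG as labelled delimited text
#'
#' Tab-separated with a header line `time <label> <label> ...`; samples
#' in microvolts. The sampling rate is recovered from the time column.
#'
#' @param rec an [eeg_recording()].
#' @param path file path (`.tsv` / `.txt`).
#' @export
write_eeg <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  tab <- data.frame(time = (seq_len(ncol(rec$samples)) - 1) / rec$rate,
                    t(rec$samples), check.names = FALSE)
  names(tab) <- c("time", rec$labels)
  utils::write.table(format(tab, digits = 10, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg
#' @export
read_eeg <- function(path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    stop("EDF input is not supported; supply labelled delimited text")
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (names(tab)[1] != "time") stop("first column must be 'time'")
  labels <- names(tab)[-1]
  if (anyDuplicated(labels)) {
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  dt <- diff(tab$time)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    stop("time column is not uniformly sampled")
  }
  eeg_recording(t(as.matrix(tab[, -1, drop = FALSE])),
                rate = 1 / dt[1], labels = labels)
}

#' Write / read the trial schedule as a BIDS-style events table
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`,
#' `stimulus_id`, `target_region1`, `target_region2`, `target_v1`,
#' `target_a1`, `target_v2`, `target_a2`, `jitter`. Reading re-validates
#' the reporting-only precedence constraint; rows out of onset order are
#' re-sorted with a warning.
#'
#' @param schedule a `trial_schedule`.
#' @param path output `.tsv` path.
#' @param half_duration the 20-s half length, used when reading.
#' @export
write_events <- function(schedule, path) {
  cols <- c("onset", "duration", "trial_type", "stimulus_id",
            "target_region1", "target_region2", "target_v1", "target_a1",
            "target_v2", "target_a2", "jitter")
  utils::write.table(as.data.frame(schedule)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, half_duration = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type", "stimulus_id")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("events table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (is.unsorted(tab$onset, strictly = TRUE)) {
    warning("events rows were not sorted by onset; re-sorting")
    tab <- tab[order(tab$onset), , drop = FALSE]
  }
  tab$trial <- seq_len(nrow(tab))
  if (!"jitter" %in% names(tab)) tab$jitter <- 0
  attr(tab, "half_duration") <- half_duration %||% (tab$duration[1] / 2)
  class(tab) <- c("trial_schedule", "data.frame")
  validate_schedule(tab)
  tab
}

#' Write / read affect report traces
#'
#' Tab-separated columns `time`, `valence`, `arousal`, `kind`; values
#' are validated to lie in [-1, 1] on load.
#'
#' @param trajectory an `affect_trajectory`.
#' @param path output `.tsv` path.
#' @export
write_reports <- function(trajectory, path) {
  tab <- data.frame(time = trajectory$time,
                    valence = trajectory$valence,
                    arousal = trajectory$arousal,
                    kind = attr(trajectory, "kind") %||% "reported")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reports
#' @export
read_reports <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("time", "valence", "arousal")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("reports table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(abs(tab$valence) > 1) || any(abs(tab$arousal) > 1)) {
    stop("affect values outside [-1, 1] in ", path)
  }
  kind <- if ("kind" %in% names(tab)) tab$kind[1] else "reported"
  affect_trajectory(tab$time, tab$valence, tab$arousal, kind = kind)
}

#' Write a cluster table as TSV
#'
#' @param clusters output of [local_maxima_table()].
#' @param path output path.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Serialises the simulation/analysis configuration, seed and package
#' version as JSON; a saved manifest plus the package suffice to re-run
#' bit-identically.
#'
#' @param config a [sim_config()].
#' @param extra optional named list of additional fields.
#' @param path optional path; when given, the JSON is written there.
#' @return the manifest list, invisibly when writing.
#' @export
run_manifest <- function(config, extra = list(), path = NULL) {
  plain <- config
  class(plain) <- NULL
  plain$coupling <- list(
    eeg_valence_gain = config$coupling$eeg_valence_gain,
    rois = lapply(config$coupling$rois, function(r) {
      list(driver = r$driver, amplitude = r$amplitude,
           n_voxels = sum(r$mask))
    }))
  man <- c(list(package = "affectfuse",
                version = as.character(utils::packageVersion("affectfuse")),
                seed = config$seed,
                timestamp = format(Sys.time(), tz = "UTC")),
           list(config = plain), extra)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(man))
  }
  man
}

#' Write / read an asymmetry series as annotated TSV
#'
#' Two tab-separated columns (`time`, `value`) preceded by comment lines
#' carrying the band definition and sample rate.
#'
#' @param asym an `asymmetry_series`.
#' @param path output `.tsv` path.
#' @export
write_asymmetry <- function(asym, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# band: %s (%g-%g Hz)", asym$band$name,
                       asym$band$low, asym$band$high),
               sprintf("# rate_hz: %g", asym$rate),
               "time\tvalue"), con)
  utils::write.table(data.frame(time = asym$times, value = asym$values),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_asymmetry
#' @export
read_asymmetry <- function(path) {
  hdr <- readLines(path, n = 2)
  bm <- regmatches(hdr[1], regexec("# band: (\\w+) \\(([0-9.]+)-([0-9.]+) Hz\\)",
                                   hdr[1]))[[1]]
  if (length(bm) != 4) stop("missing band metadata header in ", path)
  rate <- as.numeric(sub("# rate_hz: ", "", hdr[2]))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(times = tab$time, values = tab$value, rate = rate,
                 band = structure(list(name = bm[2], low = as.numeric(bm[3]),
                                       high = as.numeric(bm[4])),
                                  class = "band_definition")),
            class = "asymmetry_series")
}
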