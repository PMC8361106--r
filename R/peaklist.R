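#' Construct a centroided MS1 peak list
#'
#' A peak list is one sample's centroided MS1 observations: retention time
#' (minutes), m/z (Da) and intensity (arbitrary units), plus the ionization
#' polarity of the acquisition.
#'
#' @param sample_id Sample identifier string.
#' @param rt Retention times in minutes (>= 0).
#' @param mz m/z values (within `scan_range` when one is declared).
#' @param intensity Intensities (>= 0).
#' @param polarity `"negative"` or `"positive"`.
#' @param scan_range Optional length-2 acquisition m/z range.
#' @return A `data.frame` of class `"peaklist"` with columns `rt`, `mz`,
#'   `intensity` and attributes `sample_id`, `polarity`, `scan_range`.
#' @export
peaklist <- function(sample_id, rt, mz, intensity,
                     polarity = c("negative", "positive"),
                     scan_range = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(length(rt) == length(mz), length(mz) == length(intensity))
  if (any(rt < 0)) stop("retention times must be >= 0")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  if (!is.null(scan_range)) {
    stopifnot(length(scan_range) == 2)
    if (any(mz < scan_range[1] | mz > scan_range[2]))
      stop("m/z outside declared scan range")
  }
  structure(data.frame(rt = rt, mz = mz, intensity = intensity),
            sample_id = as.character(sample_id), polarity = polarity,
            scan_range = scan_range,
            class = c("peaklist", "data.frame"))
}

sample_id <- function(pl) attr(pl, "sample_id")
polarity <- function(pl) attr(pl, "polarity")

#' Read peak tables from delimited text
#'
#' Expects tab- or comma-delimited text with header columns `sample`,
#' `rt_min`, `mz`, `intensity`, `polarity` and returns one [peaklist()] per
#' sample.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return Named list of [peaklist()] objects.
#' @export
read_peak_table <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  needed <- c("sample", "rt_min", "mz", "intensity", "polarity")
  if (!all(needed %in% names(tab)))
    stop("peak table must have columns: ", paste(needed, collapse = ", "))
  out <- lapply(split(tab, tab$sample), function(sub) {
    pol <- unique(sub$polarity)
    if (length(pol) != 1)
      stop("sample ", sub$sample[1], " mixes polarities")
    peaklist(sub$sample[1], sub$rt_min, sub$mz, sub$intensity, pol)
  })
  out
}

#' Write peak lists to a delimited table
#'
#' @param peaklists Named list of [peaklist()] objects.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @export
write_peak_table <- function(peaklists, path, sep = "\t") {
  tab <- do.call(rbind, lapply(peaklists, function(pl) {
    data.frame(sample = sample_id(pl), rt_min = pl$rt, mz = pl$mz,
               intensity = pl$intensity, polarity = polarity(pl))
  }))
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
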