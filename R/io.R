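# Readers and writers for the plain-text formats the pipeline consumes:
# SEG-like CNV call tables, phenotype/panel tables and BED tracks.
# Internal coordinates are always 1-based inclusive; BED input (0-based
# half-open) is converted on read and back on write.

.read_table_lines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw) & !grepl("^(track|browser)\\b", raw)
  list(lines = raw[keep], lineno = which(keep))
}

.parse_coord <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || v != floor(v))
    .fail("line ", lineno, ": malformed ", what, " coordinate '", x, "'")
  v
}

#' Read per-sample CNV segment calls
#'
#' Reads a SEG-like tab-separated table with header columns
#' `sample chrom start end type copy_number n_probes` (a trailing
#' `spacing` column with the mean inter-probe distance is optional).
#' Coordinates are interpreted as 1-based inclusive; `type` must be
#' `DEL` or `DUP`; `copy_number` may be `NA` (carrier-status-only
#' platforms such as qPCR panels report no integer state, and the call
#' type is then authoritative). Lines starting with `#` are ignored.
#' Every malformed row is rejected with its line number.
#'
#' @param path Path to the calls TSV.
#' @return A `cnv_calls` data frame with columns `sample_id`, `chrom`,
#'   `start`, `end`, `cnv_type`, `copy_number`, `n_probes`,
#'   `mean_probe_spacing`.
#' @examples
#' f <- tempfile()
#' writeLines(c("sample\tchrom\tstart\tend\ttype\tcopy_number\tn_probes",
#'              "S1\tchr13\t94781525\t94797285\tDEL\t1\t12"), f)
#' calls <- read_cnv_calls(f)
#' cnv_length(calls$start, calls$end)  # 15761 bp
#' @export
read_cnv_calls <- function(path) {
  tab <- .read_table_lines(path)
  if (length(tab$lines) == 0L) .fail("empty calls file (no header): ", path)
  fields <- .split_fields(tab$lines)
  header <- tolower(fields[[1]])
  need <- c("sample", "chrom", "start", "end", "type", "copy_number", "n_probes")
  if (!all(need %in% header))
    .fail("calls header must contain: ", paste(need, collapse = " "))
  idx <- match(need, header)
  sp_idx <- match("spacing", header)

  rows <- fields[-1]
  linenos <- tab$lineno[-1]
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    ln <- linenos[i]
    if (length(f) < length(header))
      .fail("line ", ln, ": expected ", length(header), " fields, got ", length(f))
    start <- .parse_coord(f[idx[3]], "start", ln)
    end <- .parse_coord(f[idx[4]], "end", ln)
    if (end <= start)
      .fail("line ", ln, ": end (", end, ") must be greater than start (", start, ")")
    type <- toupper(f[idx[5]])
    if (!type %in% c("DEL", "DUP"))
      .fail("line ", ln, ": unknown CNV type '", f[idx[5]], "' (expected DEL or DUP)")
    cn_raw <- f[idx[6]]
    cn <- if (cn_raw %in% c("NA", ".", "")) NA_integer_ else {
      v <- suppressWarnings(as.integer(cn_raw))
      if (is.na(v) || v < 0) .fail("line ", ln, ": malformed copy_number '", cn_raw, "'")
      v
    }
    if (!is.na(cn)) {
      if (type == "DEL" && cn >= 2L)
        .fail("line ", ln, ": DEL call with copy_number ", cn, " (must be < 2)")
      if (type == "DUP" && cn <= 2L)
        .fail("line ", ln, ": DUP call with copy_number ", cn, " (must be > 2)")
    }
    np <- suppressWarnings(as.integer(f[idx[7]]))
    if (is.na(np) || np < 0) .fail("line ", ln, ": malformed n_probes '", f[idx[7]], "'")
    sp <- if (!is.na(sp_idx) && length(f) >= sp_idx)
      suppressWarnings(as.numeric(f[sp_idx])) else NA_real_
    out[[i]] <- data.frame(
      sample_id = f[idx[1]], chrom = f[idx[2]], start = start, end = end,
      cnv_type = type, copy_number = cn, n_probes = np,
      mean_probe_spacing = sp, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), chrom = character(), start = numeric(),
               end = numeric(), cnv_type = character(), copy_number = integer(),
               n_probes = integer(), mean_probe_spacing = numeric(),
               stringsAsFactors = FALSE)
  class(res) <- c("cnv_calls", "data.frame")
  res
}

#' Write CNV calls in the SEG-like dialect `read_cnv_calls` reads
#' @param calls A `cnv_calls` data frame.
#' @param path Output path.
#' @export
write_cnv_calls <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample", "chrom", "start", "end", "type",
                     "copy_number", "n_probes", "spacing"), collapse = "\t"), con)
  if (nrow(calls))
    writeLines(paste(calls$sample_id, calls$chrom,
                     format(calls$start, scientific = FALSE, trim = TRUE),
                     format(calls$end, scientific = FALSE, trim = TRUE),
                     calls$cnv_type, calls$copy_number, calls$n_probes,
                     calls$mean_probe_spacing, sep = "\t"), con)
  invisible(path)
}

#' Read a phenotype/panel table
#'
#' Columns `sample phenotype panel platform` are required; `mapd`,
#' `contrast_qc` and `batch` are optional. Phenotype must be
#' `case`/`control`; platform one of `ARRAY`, `QPCR`, `INSILICO`.
#' In-silico samples are public reference control sets, so an
#' `insilico` sample with phenotype `case` is rejected, as is any
#' duplicated sample id.
#'
#' @param path Path to the phenotype TSV.
#' @return A `cnv_phenotypes` data frame with columns `sample_id`,
#'   `phenotype` (`CASE`/`CONTROL`), `panel_id`, `platform`, `mapd`,
#'   `contrast_qc`, `batch_id`.
#' @export
read_phenotypes <- function(path) {
  tab <- .read_table_lines(path)
  if (length(tab$lines) == 0L) .fail("empty phenotype file: ", path)
  fields <- .split_fields(tab$lines)
  header <- tolower(fields[[1]])
  need <- c("sample", "phenotype", "panel", "platform")
  if (!all(need %in% header))
    .fail("phenotype header must contain: ", paste(need, collapse = " "))
  idx <- match(need, header)
  opt <- match(c("mapd", "contrast_qc", "batch"), header)

  rows <- fields[-1]
  linenos <- tab$lineno[-1]
  get_num <- function(f, j) {
    if (is.na(j) || length(f) < j || f[j] %in% c("NA", ".", "")) NA_real_
    else suppressWarnings(as.numeric(f[j]))
  }
  out <- lapply(seq_along(rows), function(i) {
    f <- rows[[i]]
    ln <- linenos[i]
    if (length(f) < length(need))
      .fail("line ", ln, ": expected at least ", length(need), " fields")
    phe <- toupper(f[idx[2]])
    if (!phe %in% c("CASE", "CONTROL"))
      .fail("line ", ln, ": phenotype must be case or control, got '", f[idx[2]], "'")
    plat <- toupper(f[idx[4]])
    if (!plat %in% c("ARRAY", "QPCR", "INSILICO"))
      .fail("line ", ln, ": unknown platform '", f[idx[4]], "'")
    if (plat == "INSILICO" && phe == "CASE")
      .fail("line ", ln, ": in-silico samples must be controls")
    batch <- if (!is.na(opt[3]) && length(f) >= opt[3]) f[opt[3]] else NA_character_
    data.frame(sample_id = f[idx[1]], phenotype = phe, panel_id = f[idx[3]],
               platform = plat, mapd = get_num(f, opt[1]),
               contrast_qc = get_num(f, opt[2]), batch_id = batch,
               stringsAsFactors = FALSE)
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), phenotype = character(),
               panel_id = character(), platform = character(),
               mapd = numeric(), contrast_qc = numeric(),
               batch_id = character(), stringsAsFactors = FALSE)
  dup <- res$sample_id[duplicated(res$sample_id)]
  if (length(dup))
    .fail("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  class(res) <- c("cnv_phenotypes", "data.frame")
  res
}

#' Write a phenotype table in the dialect `read_phenotypes` reads
#' @param phenotypes A `cnv_phenotypes` data frame.
#' @param path Output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample", "phenotype", "panel", "platform",
                     "mapd", "contrast_qc", "batch"), collapse = "\t"), con)
  if (nrow(phenotypes))
    writeLines(paste(phenotypes$sample_id, tolower(phenotypes$phenotype),
                     phenotypes$panel_id, tolower(phenotypes$platform),
                     phenotypes$mapd, phenotypes$contrast_qc,
                     phenotypes$batch_id, sep = "\t"), con)
  invisible(path)
}

#' Construct a genomic interval track
#'
#' A track is an ordered set of labelled 1-based inclusive intervals,
#' used for array probe positions, assembly gaps and known common CNVs.
#'
#' @param chrom,start,end Parallel vectors of 1-based inclusive intervals.
#' @param label Optional per-interval label (e.g. `DEL`/`DUP` on a common
#'   CNV track makes the common-CNV filter type-aware).
#' @return A `genomic_track` data frame sorted by (chrom, start).
#' @export
genomic_track <- function(chrom = character(), start = numeric(),
                          end = numeric(), label = NA_character_) {
  if (length(start) && any(start < 1)) .fail("track start coordinates must be >= 1")
  if (any(end < start)) .fail("track intervals must have end >= start")
  res <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end),
                    label = rep_len(as.character(label), length(chrom)),
                    stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("genomic_track", "data.frame")
  res
}

#' Read a BED track
#'
#' Standard BED is 0-based half-open; intervals are converted to the
#' package's 1-based inclusive convention on read (`start + 1`, `end`),
#' so the BED line `chr13 94781524 94797285` becomes the interval
#' chr13:94,781,525-94,797,285. Unsorted input is accepted and sorted;
#' overlapping intervals are preserved, not merged. Negative
#' coordinates are rejected.
#'
#' @param path Path to a BED file (3 columns, optional 4th name column).
#' @return A `genomic_track` data frame.
#' @export
read_bed_track <- function(path) {
  tab <- .read_table_lines(path)
  if (length(tab$lines) == 0L)
    return(genomic_track())
  fields <- .split_fields(tab$lines)
  out <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    ln <- tab$lineno[i]
    if (length(f) < 3L) .fail("line ", ln, ": BED needs >= 3 columns")
    s <- .parse_coord(f[2], "start", ln)
    e <- .parse_coord(f[3], "end", ln)
    if (s < 0 || e < 0) .fail("line ", ln, ": negative BED coordinate")
    if (e <= s) .fail("line ", ln, ": BED end must exceed start")
    data.frame(chrom = f[1], start = s + 1, end = e,
               label = if (length(f) >= 4L) f[4] else NA_character_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  genomic_track(res$chrom, res$start, res$end, res$label)
}

#' Write a track as BED (converting back to 0-based half-open)
#' @param track A `genomic_track`.
#' @param path Output path.
#' @export
write_bed_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(track)) {
    lab <- ifelse(is.na(track$label), ".", track$label)
    writeLines(paste(track$chrom,
                     format(track$start - 1, scientific = FALSE, trim = TRUE),
                     format(track$end, scientific = FALSE, trim = TRUE),
                     lab, sep = "\t"), con)
  }
  invisible(path)
}
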