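# seqio: FASTA / region-map / table input-output and the clone data model.
#
# A clone set is a tibble with columns clone_id, individual_id, tissue,
# sequence and (optionally) group_label. FASTA headers use the dialect
# "clone_id|individual_id|tissue"; absent fields default to "".

#' Read cDNA clones from a FASTA file
#'
#' Headers are parsed as `clone_id|individual_id|tissue`; missing fields
#' default to the empty string. Sequences are uppercased and RNA `U` is
#' converted to `T`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `clone_id`, `individual_id`, `tissue`,
#'   `sequence`.
#' @export
read_clone_fasta <- function(path) {
  if (!file.exists(path)) stop_shm("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_shm("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  if (length(set) == 0) stop_shm("empty dataset: no FASTA records in ", path)
  seqs <- chartr("U", "T", toupper(as.character(set)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop_shm("non-nucleotide characters in record(s): ",
             paste(names(set)[bad], collapse = ", "))
  }
  fields <- strsplit(names(set), "|", fixed = TRUE)
  pick <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) trimws(f[[i]]) else ""
  }, character(1))
  out <- tibble::tibble(
    clone_id = pick(1), individual_id = pick(2), tissue = pick(3),
    sequence = unname(seqs)
  )
  if (anyDuplicated(out$clone_id)) {
    stop_shm("duplicate clone_id in ", path)
  }
  out
}

#' Write a clone set to FASTA
#'
#' Inverse of [read_clone_fasta()]: a write/read round trip reproduces
#' identical ids and sequences.
#'
#' @param clones Clone tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clone_fasta <- function(clones, path) {
  check_clone_tbl(clones)
  ind <- if ("individual_id" %in% names(clones)) clones$individual_id else ""
  tis <- if ("tissue" %in% names(clones)) clones$tissue else ""
  hdr <- paste(clones$clone_id, ind, tis, sep = "|")
  hdr <- sub("\\|+$", "", hdr)
  set <- Biostrings::BStringSet(clones$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a region map
#'
#' The file is tab-separated with rows `name<TAB>start<TAB>end` (0-based
#' half-open) plus one row `frame_offset<TAB>k`. Region names are restricted
#' to FR1-4, CDR1-3 and the constant subregions C-Ig, C-CP, C-TM, C-CYT.
#' Regions are sorted on load; overlaps are rejected.
#'
#' @param path Path to the region-map file.
#' @return An object of class `shm_region_map`: a list with `frame_offset`
#'   (integer 0-2) and `regions` (tibble `name`, `start`, `end`).
#' @export
read_region_map <- function(path) {
  if (!file.exists(path)) stop_shm("region map not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("name", "start", "end"),
                           fill = TRUE, stringsAsFactors = FALSE)
  fo_row <- raw$name == "frame_offset"
  frame_offset <- 0L
  if (any(fo_row)) frame_offset <- as.integer(raw$start[fo_row][1])
  regions <- raw[!fo_row, , drop = FALSE]
  region_map(regions = tibble::tibble(
    name = regions$name,
    start = as.integer(regions$start),
    end = as.integer(regions$end)
  ), frame_offset = frame_offset)
}

#' Construct and validate a region map
#'
#' @param regions Tibble with columns `name`, `start`, `end` (0-based
#'   half-open).
#' @param frame_offset Integer 0-2, offset of the first full codon.
#' @return An `shm_region_map` object.
#' @export
region_map <- function(regions, frame_offset = 0L) {
  frame_offset <- as.integer(frame_offset)
  if (is.na(frame_offset) || frame_offset < 0 || frame_offset > 2) {
    stop_shm("frame_offset must be 0, 1 or 2")
  }
  unknown <- setdiff(regions$name, VALID_REGION_NAMES)
  if (length(unknown)) stop_shm("unknown region name(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(regions$name)) stop_shm("duplicate region names")
  if (any(regions$end <= regions$start)) {
    bad <- regions$name[regions$end <= regions$start]
    stop_shm("region end must exceed start: ", paste(bad, collapse = ", "))
  }
  regions <- dplyr::arrange(regions, .data$start)
  if (nrow(regions) > 1 &&
      any(regions$start[-1] < regions$end[-nrow(regions)])) {
    stop_shm("regions overlap after sorting")
  }
  structure(list(frame_offset = frame_offset, regions = regions),
            class = "shm_region_map")
}

#' @export
print.shm_region_map <- function(x, ...) {
  cat("<shm_region_map> frame_offset =", x$frame_offset, "\n")
  print(x$regions)
  invisible(x)
}

# region name for 0-based positions, NA outside every region
region_of <- function(positions, rmap) {
  if (is.null(rmap)) return(rep(NA_character_, length(positions)))
  out <- rep(NA_character_, length(positions))
  for (i in seq_len(nrow(rmap$regions))) {
    hit <- positions >= rmap$regions$start[i] & positions < rmap$regions$end[i]
    out[hit] <- rmap$regions$name[i]
  }
  out
}

#' Write stage outputs as a deterministic table bundle
#'
#' Each element of `results` is written as `<name>.tsv` with fixed column
#' order; elements named `*_bed` are written as BED (0-based half-open).
#' A `run_metadata.txt` file records parameters and seed so a bundle is
#' reproducible from its metadata alone. Output is byte-identical across
#' runs on identical inputs.
#'
#' @param results Named list of tibbles.
#' @param out_dir Output directory (created if absent).
#' @param metadata Named list of parameters/seed/version to record.
#' @return Character vector of files written, invisibly.
#' @export
write_tables <- function(results, out_dir, metadata = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_shm("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stop_shm("output directory not writable: ", out_dir)
  }
  paths <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.null(x)) next
    if (grepl("_bed$", nm)) {
      p <- file.path(out_dir, paste0(sub("_bed$", "", nm), ".bed"))
      readr::write_tsv(x, p, col_names = FALSE, progress = FALSE)
    } else {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      readr::write_tsv(x, p, progress = FALSE)
    }
    paths <- c(paths, p)
  }
  meta_path <- file.path(out_dir, "run_metadata.txt")
  meta_lines <- c(
    paste0("package_version\t", as.character(utils::packageVersion("tcrshm"))),
    vapply(names(metadata), function(k) {
      paste0(k, "\t", paste(format(metadata[[k]]), collapse = ","))
    }, character(1))
  )
  writeLines(meta_lines, meta_path)
  invisible(c(paths, meta_path))
}

#' Convert motif hits to a BED-shaped tibble
#'
#' Windows are 0-based half-open; thickStart/thickEnd mark the single
#' mutable base of each hit.
#'
#' @param hits Motif-hit tibble from [scan_motifs()].
#' @param chrom Reference name to place in column 1.
#' @return Tibble in BED6+ column order.
#' @export
motif_hits_to_bed <- function(hits, chrom = "ref") {
  tibble::tibble(
    chrom = chrom,
    chromStart = hits$window_start,
    chromEnd = hits$window_end,
    name = hits$motif_class,
    score = 0L,
    strand = "+",
    thickStart = hits$mutable_position,
    thickEnd = hits$mutable_position + 1L
  )
}
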