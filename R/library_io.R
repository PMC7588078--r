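#' Read an sgRNA library table
#'
#' Reads the tab-separated catalogue of an sgRNA library: one row per sgRNA
#' with its identifier, target (a gene symbol, or the marker `"NTC"` for
#' non-targeting controls), the targeted transcription start site, the 5'
#' spacer sequence and the library it belongs to. Screens built from several
#' sub-genome libraries keep one table with distinct `library_id` values;
#' all downstream scoring is done library by library because each library
#' carries its own non-targeting controls.
#'
#' @param path Path to a TSV file with header columns `sgrna_id`, `target`,
#'   `tss_id`, `spacer`, `library_id`.
#' @return A validated tibble with those five character columns. Non-targeting
#'   controls are the rows with `target == "NTC"`; their `tss_id` is `NA`.
#' @seealso [validate_library()], [read_count_table()]
#' @export
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' readr::write_tsv(build_library(2, 2, 1, seed = 1), path)
#' read_library_table(path)
read_library_table <- function(path) {
  if (!file.exists(path)) {
    stop_sortscreen(paste0("library table not found: ", path))
  }
  lib <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  )
  required <- c("sgrna_id", "target", "tss_id", "spacer", "library_id")
  missing <- setdiff(required, names(lib))
  if (length(missing) > 0) {
    stop_sortscreen(
      paste0("library table lacks column(s): ", paste(missing, collapse = ", ")),
      class = "sortscreen_format_error"
    )
  }
  validate_library(as_tibble(lib[required]))
}

#' Validate an sgRNA library table
#'
#' Checks the library invariants: unique sgRNA identifiers within each
#' library, spacers containing only A/C/G/T with a single common length per
#' library, and every row being either gene-targeting or a non-targeting
#' control (`target == "NTC"`).
#'
#' @param library A tibble as returned by [read_library_table()] or
#'   [build_library()].
#' @return The library, invisibly unchanged, for piping.
#' @export
validate_library <- function(library) {
  library <- as_tibble(library)
  dup <- library |>
    dplyr::count(.data$library_id, .data$sgrna_id) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_sortscreen(
      paste0("duplicated sgrna_id within a library: ",
             paste(utils::head(dup$sgrna_id, 3), collapse = ", ")),
      class = "sortscreen_format_error"
    )
  }
  if (any(is.na(library$spacer)) || any(grepl("[^ACGT]", library$spacer))) {
    stop_sortscreen("spacers must contain only A/C/G/T",
                    class = "sortscreen_format_error")
  }
  len_per_lib <- tapply(nchar(library$spacer), library$library_id,
                        function(l) length(unique(l)))
  if (any(len_per_lib > 1)) {
    stop_sortscreen("all spacers within one library must have equal length",
                    class = "sortscreen_format_error")
  }
  if (any(is.na(library$target) | library$target == "")) {
    stop_sortscreen("every entry needs a target gene or the NTC marker",
                    class = "sortscreen_format_error")
  }
  library
}

is_ntc <- function(library) library$target == "NTC"

#' Count sgRNAs in raw screen reads
#'
#' Assigns each sequencing read of one sorted fraction to a library spacer.
#' The read is cropped to the window starting at `crop_offset` (0-based) with
#' the library's spacer length, and matched against the spacers either
#' exactly or allowing one mismatch (Hamming distance 1). Reads matching no
#' spacer are counted unassigned; reads whose minimal distance is attained by
#' more than one spacer are discarded as ambiguous so that counts stay
#' integral and conservative. Base qualities are ignored.
#'
#' @param fastq Path to a FASTQ file (one sorted fraction).
#' @param library Library table (see [read_library_table()]).
#' @param crop_offset Number of bases to skip at the 5' end of each read
#'   before the spacer window (>= 0).
#' @param max_mismatch Either 0 (exact matching) or 1.
#' @return A list with `counts`, a tibble of `sgrna_id` and `count` covering
#'   every library sgRNA (zeros included), and `report`, a one-row tibble
#'   with `n_reads`, `n_assigned`, `n_unassigned`, `n_ambiguous`
#'   (the three always sum to `n_reads`).
#' @export
count_sgrnas <- function(fastq, library, crop_offset = 0L, max_mismatch = 0L) {
  library <- validate_library(library)
  if (nrow(library) == 0) {
    stop_sortscreen("cannot count against an empty library",
                    class = "sortscreen_config_error")
  }
  if (!max_mismatch %in% c(0L, 1L)) {
    stop_sortscreen("max_mismatch must be 0 or 1",
                    class = "sortscreen_config_error")
  }
  crop_offset <- as.integer(crop_offset)
  stopifnot(crop_offset >= 0L)
  spacer_len <- nchar(library$spacer[1])
  spacers <- library$spacer
  if (anyDuplicated(spacers)) {
    stop_sortscreen("spacers must be unique for read assignment",
                    class = "sortscreen_config_error")
  }

  reads <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  n_reads <- length(reads)
  assigned <- integer(nrow(library))
  n_ambiguous <- 0L
  long_enough <- nchar(reads) >= crop_offset + spacer_len

  windows <- substr(reads[long_enough], crop_offset + 1L,
                    crop_offset + spacer_len)
  hit <- match(windows, spacers)
  if (max_mismatch == 1L && anyNA(hit)) {
    miss <- which(is.na(hit))
    for (i in miss) {
      cand <- hamming1_matches(windows[i], spacers)
      if (length(cand) == 1L) {
        hit[i] <- cand
      } else if (length(cand) > 1L) {
        n_ambiguous <- n_ambiguous + 1L
      }
    }
  }
  tab <- tabulate(hit[!is.na(hit)], nbins = nrow(library))
  n_assigned <- sum(tab)
  report <- tibble(
    n_reads = n_reads,
    n_assigned = as.integer(n_assigned),
    n_unassigned = n_reads - as.integer(n_assigned) - n_ambiguous,
    n_ambiguous = n_ambiguous
  )
  list(
    counts = tibble(sgrna_id = library$sgrna_id, count = as.integer(tab)),
    report = report
  )
}

# indices of spacers at Hamming distance exactly <= 1 from `window`,
# found by looking up all single-base substitutions in the spacer set
hamming1_matches <- function(window, spacers) {
  exact <- match(window, spacers)
  if (!is.na(exact)) return(exact)
  L <- nchar(window)
  bases <- c("A", "C", "G", "T")
  variants <- character(3L * L)
  k <- 0L
  for (pos in seq_len(L)) {
    cur <- substr(window, pos, pos)
    for (b in bases[bases != cur]) {
      k <- k + 1L
      v <- window
      substr(v, pos, pos) <- b
      variants[k] <- v
    }
  }
  m <- match(variants, spacers)
  sort(unique(m[!is.na(m)]))
}

#' Read a per-fraction sgRNA count table
#'
#' Reads a TSV with an `sgrna_id` column followed by one non-negative integer
#' column per sorted fraction (typically `low`, `medium`, `high`). When a
#' library table is supplied, sgRNAs absent from the file are added with zero
#' counts (the downstream statistics need the complete row set) and unknown
#' sgRNA identifiers raise an error.
#'
#' @param path Path to the TSV file.
#' @param library Optional library table used to validate and complete the
#'   row set.
#' @return A tibble of `sgrna_id` plus one integer column per sample.
#' @export
read_count_table <- function(path, library = NULL) {
  counts <- readr::read_tsv(path, col_types = readr::cols(
    sgrna_id = readr::col_character(),
    .default = readr::col_double()
  ))
  if (!"sgrna_id" %in% names(counts)) {
    stop_sortscreen("count table needs an sgrna_id column",
                    class = "sortscreen_format_error")
  }
  validate_counts(as_tibble(counts), library)
}

#' Write a per-fraction sgRNA count table
#'
#' @param counts Count tibble (see [read_count_table()]).
#' @param path Output path; written as TSV with header.
#' @return `counts`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(counts)
}

#' Validate (and complete) a count table against a library
#'
#' @inheritParams read_count_table
#' @param counts Count tibble with `sgrna_id` and sample columns.
#' @return The validated tibble; with `library` given, rows are ordered as in
#'   the library and missing sgRNAs are zero-filled.
#' @export
validate_counts <- function(counts, library = NULL) {
  samples <- setdiff(names(counts), "sgrna_id")
  vals <- as.matrix(counts[samples])
  if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals))) {
    stop_sortscreen("counts must be non-negative integers",
                    class = "sortscreen_format_error")
  }
  if (anyDuplicated(counts$sgrna_id)) {
    stop_sortscreen("duplicated sgrna_id in count table",
                    class = "sortscreen_format_error")
  }
  counts <- mutate(counts, across(all_of(samples), as.integer))
  if (!is.null(library)) {
    unknown <- setdiff(counts$sgrna_id, library$sgrna_id)
    if (length(unknown) > 0) {
      stop_sortscreen(
        paste0("count table contains sgRNAs absent from the library: ",
               paste(utils::head(unknown, 3), collapse = ", ")),
        class = "sortscreen_validation_error"
      )
    }
    full <- tibble(sgrna_id = library$sgrna_id)
    counts <- left_join(full, counts, by = "sgrna_id")
    counts[samples] <- lapply(counts[samples], function(x) {
      x[is.na(x)] <- 0L
      x
    })
  }
  counts
}

#' Synthesize a FASTQ file from a count vector
#'
#' Writes one read per tallied sgRNA copy: `crop_offset` filler bases, then
#' the spacer, then filler up to `read_length`. Used to build end-to-end
#' fixtures in which [count_sgrnas()] must recover the input counts exactly.
#'
#' @param counts Tibble with `sgrna_id` and a `count` column (a single
#'   fraction), or a named integer vector.
#' @param library Library table supplying the spacers.
#' @param path Output FASTQ path.
#' @param crop_offset Filler bases to prepend (default 0).
#' @param read_length Total read length; defaults to
#'   `crop_offset + spacer length`.
#' @param shuffle Shuffle read order (read order never affects counting).
#' @param seed Seed for the shuffle.
#' @return `path`, invisibly.
#' @export
synthesize_fastq <- function(counts, library, path, crop_offset = 0L,
                             read_length = NULL, shuffle = FALSE, seed = NULL) {
  if (!is.data.frame(counts)) {
    counts <- tibble(sgrna_id = names(counts), count = as.integer(counts))
  }
  spacer <- library$spacer[match(counts$sgrna_id, library$sgrna_id)]
  if (anyNA(spacer)) {
    stop_sortscreen("counts refer to sgRNAs absent from the library",
                    class = "sortscreen_validation_error")
  }
  spacer_len <- nchar(library$spacer[1])
  if (is.null(read_length)) read_length <- crop_offset + spacer_len
  stopifnot(read_length >= crop_offset + spacer_len)
  seqs <- rep(spacer, counts$count)
  if (shuffle && length(seqs) > 1) {
    seqs <- with_seed_(seed, sample(seqs))
  }
  pre <- strrep("G", crop_offset)
  post <- strrep("A", read_length - crop_offset - spacer_len)
  ids <- paste0("@read_", seq_along(seqs))
  qual <- strrep("I", read_length)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs) > 0) {
    writeLines(paste(ids, paste0(pre, seqs, post), "+", qual, sep = "\n"), con)
  }
  invisible(path)
}
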