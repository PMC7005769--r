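#' Read a classic DSSP file into a per-residue reference table
#'
#' Parses the residue block of a classic DSSP output file (the block headed
#' by `"  #  RESIDUE AA"`), taking the author residue numbering, the chain
#' id, the amino acid, and the eight-state secondary-structure code at its
#' fixed column. Residues DSSP leaves unlabelled (a blank structure column)
#' are assigned coil (`"C"`); chain-break rows (`"!"` in the amino-acid
#' column) carry no residue and are skipped.
#'
#' @param path Path to a DSSP file (v2 and v3 `mkdssp` headers are both
#'   accepted; only the residue block layout is relied upon).
#' @param chain Optional single chain identifier. Required when the file
#'   contains more than one chain.
#' @param protein_id Identifier recorded for this structure; defaults to the
#'   file name without extension.
#'
#' @return A tibble with one row per residue: `residue_id` (author
#'   numbering, strictly increasing; gaps allowed), `chain`, `aa`
#'   (one-letter amino-acid code), and `label` (Q8 code). The protein id is
#'   attached as attribute `"protein_id"`.
#' @export
read_dssp <- function(path, chain = NULL, protein_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE AA", lines)
  if (length(hdr) == 0) {
    abort(sprintf("'%s' has no DSSP residue block (no '  #  RESIDUE AA' header line)", path))
  }
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  pad <- function(x, n) formatC(x, width = -n)

  recs <- purrr::map(seq_along(body), function(i) {
    ln <- pad(body[i], 17L)
    aa <- substr(ln, 14L, 14L)
    if (aa == "!") return(NULL)  # chain break, no residue
    code <- substr(ln, 17L, 17L)
    if (code == " ") code <- "C"
    if (!code %in% Q8_STATES) {
      abort(sprintf(
        "unknown DSSP structure code '%s' at line %d of '%s'",
        code, hdr[1] + i, path
      ))
    }
    resnum <- suppressWarnings(as.integer(substr(ln, 6L, 10L)))
    if (is.na(resnum)) {
      abort(sprintf("unparseable residue number at line %d of '%s'", hdr[1] + i, path))
    }
    tibble::tibble(
      residue_id = resnum,
      chain = substr(ln, 12L, 12L),
      aa = aa,
      label = code
    )
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) abort(sprintf("'%s' contains no residues", path))

  chains <- unique(out$chain)
  if (!is.null(chain)) {
    out <- dplyr::filter(out, .data$chain == !!chain)
    if (nrow(out) == 0) abort(sprintf("chain '%s' not found in '%s'", chain, path))
  } else if (length(chains) > 1) {
    abort(sprintf(
      "'%s' contains %d chains (%s); supply `chain`",
      path, length(chains), paste(chains, collapse = ", ")
    ))
  }
  if (is.unsorted(out$residue_id, strictly = TRUE)) {
    abort(sprintf("residue numbering in '%s' is not strictly increasing", path))
  }
  attr(out, "protein_id") <- protein_id %||%
    sub("\\.[^.]*$", "", basename(path))
  out
}

#' Read and write a secondary-structure label trajectory
#'
#' A label trajectory holds one Q8 secondary-structure code per residue per
#' trajectory frame. On disk it is a TSV whose first line is `frame`
#' followed by the residue ids, and whose subsequent rows give the frame
#' time in picoseconds followed by one code per residue; `-` is accepted as
#' a synonym for coil and normalized to `C` on read.
#'
#' @param path File to read from or write to.
#' @return `read_label_matrix()` returns a long tibble with columns `frame`
#'   (1-based frame index), `time_ps`, `residue_id`, and `label`.
#' @export
read_label_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) abort(sprintf("'%s' has no frame rows", path))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "frame") {
    abort(sprintf("'%s': first header field must be 'frame', got '%s'", path, header[1]))
  }
  residue_ids <- as.integer(header[-1])
  if (anyNA(residue_ids)) abort(sprintf("'%s': non-integer residue id in header", path))
  n_res <- length(residue_ids)

  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != n_res + 1L)) {
    bad <- which(widths != n_res + 1L)[1]
    abort(sprintf(
      "'%s': row %d has %d fields, expected %d",
      path, bad, widths[bad], n_res + 1L
    ))
  }
  times <- as.numeric(vapply(rows, `[`, character(1), 1L))
  if (anyNA(times) || any(times < 0)) {
    abort(sprintf("'%s': frame times must be non-negative numbers", path))
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort(sprintf("'%s': frame times are not strictly increasing", path))
  }
  labels <- matrix(
    unlist(lapply(rows, `[`, -1L), use.names = FALSE),
    nrow = length(rows), byrow = TRUE
  )
  labels[labels == "-"] <- "C"
  check_q8(labels, sprintf("'%s': labels", path))

  tibble::tibble(
    frame = rep(seq_along(times), each = n_res),
    time_ps = rep(times, each = n_res),
    residue_id = rep(residue_ids, times = length(times)),
    label = as.vector(t(labels))
  )
}

#' @rdname read_label_matrix
#' @param traj A label-trajectory tibble as returned by
#'   [read_label_matrix()] or [sim_trajectory()].
#' @export
write_label_matrix <- function(traj, path) {
  wide <- traj_matrix(traj)
  header <- paste(c("frame", colnames(wide)), collapse = "\t")
  times <- attr(wide, "time_ps")
  body <- vapply(seq_len(nrow(wide)), function(i) {
    paste(c(format(times[i], trim = TRUE, scientific = FALSE), wide[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

# frames x residues character matrix from the long form; residue ids as
# column names, frame times in attr "time_ps".
traj_matrix <- function(traj) {
  frames <- sort(unique(traj$frame))
  ids <- unique(traj$residue_id)
  m <- matrix(
    traj$label[order(traj$frame, match(traj$residue_id, ids))],
    nrow = length(frames), byrow = TRUE,
    dimnames = list(NULL, as.character(ids))
  )
  times <- traj$time_ps[match(frames, traj$frame)]
  attr(m, "time_ps") <- times
  m
}

#' Read a secondary-structure prediction table
#'
#' Reads per-residue predictor output in the PSIPRED `.ss2` layout for
#' three-state predictions (`idx aa label p_C p_H p_E`) or an eight-column
#' variant for eight-state predictions (probabilities ordered
#' `H,G,I,E,B,T,S,C`). Lines starting with `#` are comments. Probability
#' rows whose sum lies in `[0.99, 1.01]` are renormalized to sum to one;
#' anything further off is an error. The predicted label is recomputed as
#' the argmax of the probabilities (ties resolved by the canonical class
#' order); when it disagrees with the label in the file, a warning is
#' issued and the file label is kept.
#'
#' @param path Path to a whitespace-delimited prediction table.
#' @param scheme `"q3"` or `"q8"`.
#' @param predictor Optional predictor name, recorded as attribute
#'   `"predictor_name"`.
#' @return A tibble with `residue_id`, `aa`, `label`, and one `p_<state>`
#'   column per class in canonical order.
#' @export
read_prediction_table <- function(path, scheme = c("q3", "q8"), predictor = NULL) {
  scheme <- match.arg(scheme)
  states <- if (scheme == "q3") Q3_STATES else Q8_STATES
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) abort(sprintf("'%s' has no data rows", path))
  fields <- strsplit(lines, "[ \t]+")
  want <- 3L + length(states)
  widths <- lengths(fields)
  if (any(widths != want)) {
    bad <- which(widths != want)[1]
    abort(sprintf("'%s': row %d has %d fields, expected %d", path, bad, widths[bad], want))
  }
  mat <- do.call(rbind, fields)
  probs <- matrix(as.numeric(mat[, -(1:3), drop = FALSE]), nrow = nrow(mat))
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    bad <- which(apply(probs, 1, function(p) anyNA(p) || any(p < 0 | p > 1)))[1]
    abort(sprintf("'%s': probability outside [0,1] at row %d", path, bad))
  }
  sums <- rowSums(probs)
  off <- which(sums < 0.99 | sums > 1.01)
  if (length(off) > 0) {
    abort(sprintf(
      "'%s': probabilities at row %d sum to %.4f, outside [0.99, 1.01]",
      path, off[1], sums[off[1]]
    ))
  }
  probs <- probs / sums
  file_label <- mat[, 3]
  bad_lab <- setdiff(unique(file_label), states)
  if (length(bad_lab) > 0) {
    abort(sprintf("'%s': label(s) outside the %s alphabet: %s",
                  path, toupper(scheme), paste(bad_lab, collapse = ", ")))
  }
  argmax_label <- states[apply(probs, 1, which.max)]
  mismatch <- which(argmax_label != file_label)
  if (length(mismatch) > 0) {
    warn(sprintf(
      "'%s': file label differs from probability argmax at %d position(s) (first: row %d, file '%s' vs argmax '%s'); keeping file labels",
      path, length(mismatch), mismatch[1], file_label[mismatch[1]], argmax_label[mismatch[1]]
    ))
  }
  out <- tibble::tibble(
    residue_id = as.integer(mat[, 1]),
    aa = mat[, 2],
    label = file_label
  )
  for (j in seq_along(states)) out[[paste0("p_", states[j])]] <- probs[, j]
  attr(out, "scheme") <- scheme
  attr(out, "predictor_name") <- predictor
  out
}

#' Read a per-residue disorder prediction table
#'
#' Reads IUPred-style output: `#`-prefixed comment lines followed by
#' whitespace- or tab-delimited rows of position, amino acid, and a
#' disorder score. Scores must already lie in `[0, 1]`; out-of-range values
#' are rejected, not clamped.
#'
#' @param path Path to the table.
#' @param predictor Optional predictor name, recorded as attribute
#'   `"predictor_name"`.
#' @return A tibble with columns `residue_id`, `aa`, `score`.
#' @export
read_disorder_table <- function(path, predictor = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) abort(sprintf("'%s' has no data rows", path))
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 3)) {
    bad <- which(lengths(fields) < 3)[1]
    abort(sprintf("'%s': row %d has fewer than 3 fields", path, bad))
  }
  mat <- do.call(rbind, lapply(fields, `[`, 1:3))
  scores <- as.numeric(mat[, 3])
  if (anyNA(scores)) {
    abort(sprintf("'%s': unparseable score at row %d", path, which(is.na(scores))[1]))
  }
  oob <- which(scores < 0 | scores > 1)
  if (length(oob) > 0) {
    abort(sprintf(
      "'%s': disorder score %.3f at position %s is outside [0,1]",
      path, scores[oob[1]], mat[oob[1], 1]
    ))
  }
  out <- tibble::tibble(
    residue_id = as.integer(mat[, 1]),
    aa = mat[, 2],
    score = scores
  )
  attr(out, "predictor_name") <- predictor
  out
}

#' Read sequences from a FASTA file
#'
#' Sequence records are returned in file order with the id taken as the
#' first whitespace-delimited token after `>`; residues are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    abort(sprintf("'%s': record '%s' has an empty sequence", path, ids[!nzchar(seqs)][1]))
  }
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write and read region sets as BED-style tables
#'
#' Regions are 1-based inclusive residue intervals in memory; on disk they
#' use the BED convention (0-based half-open start/end). The file is a TSV
#' with a header row `protein_id start end kind score`.
#'
#' @param regions A region tibble with columns `protein_id`, `start`,
#'   `end`, `kind`, `score` (1-based inclusive coordinates).
#' @param path File to write to or read from.
#' @return `write_regions()` invisibly returns `path`; `read_regions()`
#'   returns the region tibble with in-memory (1-based inclusive)
#'   coordinates.
#' @export
write_regions <- function(regions, path) {
  regions <- validate_regions(regions)
  bed <- dplyr::mutate(regions, start = .data$start - 1L)
  readr::write_tsv(bed[, c("protein_id", "start", "end", "kind", "score")], path)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      kind = readr::col_character(),
      score = readr::col_double()
    )
  )
  validate_regions(dplyr::mutate(bed, start = .data$start + 1L))
}

validate_regions <- function(regions) {
  regions <- tibble::as_tibble(regions)
  need <- c("protein_id", "start", "end", "kind", "score")
  missing <- setdiff(need, names(regions))
  if (length(missing) > 0) {
    abort(sprintf("region table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (any(regions$start > regions$end)) {
    abort("region start exceeds end")
  }
  if (any(regions$start < 1)) abort("region coordinates must be >= 1 (1-based inclusive)")
  dplyr::arrange(regions, .data$protein_id, .data$kind, .data$start)
}

empty_regions <- function() {
  tibble::tibble(
    protein_id = character(), start = integer(), end = integer(),
    kind = character(), score = double()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
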