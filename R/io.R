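#' Read a BED file of peaks
#'
#' Parses BED3/BED5 lines into a peak data frame, preserving the 0-based
#' half-open coordinates. `track`, `browser` and `#` comment lines are
#' skipped. Column 4 (name) and column 5 (score) are kept when present;
#' the score is stored as the peak `signal` (0 when absent).
#'
#' @param path path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `signal`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), signal = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("fewer than 3 fields at line %d", lineno[which(nf < 3L)[1L]]),
         call. = FALSE)
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- suppressWarnings(as.numeric(get(2L)))
  end <- suppressWarnings(as.numeric(get(3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad)) {
    stop(sprintf("non-integer coordinates at line %d", lineno[bad[1L]]),
         call. = FALSE)
  }
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stop(sprintf("start >= end at line %d", lineno[bad[1L]]), call. = FALSE)
  }
  name <- get(4L)
  signal <- suppressWarnings(as.numeric(get(5L)))
  signal[is.na(signal)] <- 0
  if (any(signal < 0)) stop("peak signal must be nonnegative", call. = FALSE)
  data.frame(chrom = get(1L), start = start, end = end,
             name = ifelse(is.na(name) | name == ".", NA_character_, name),
             signal = signal, stringsAsFactors = FALSE)
}

#' Write peaks as BED
#'
#' @param peaks peak data frame (`chrom`, `start`, `end`, optional `name`,
#'   `signal`).
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  peaks <- validate_intervals(peaks, "peak")
  name <- if (!is.null(peaks$name)) ifelse(is.na(peaks$name), ".", peaks$name) else "."
  signal <- peaks$signal %||% rep(0, nrow(peaks))
  df <- data.frame(peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                   name, signal)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE loop file into a loop library
#'
#' Expects the 8-column BEDPE dialect emitted downstream of anchor-based
#' HiChIP loop callers: chrom1, start1, end1, chrom2, start2, end2, name,
#' count — where the score column holds the mated paired-end read count.
#' Inter-chromosomal rows are dropped (with a message reporting how many);
#' anchor pairs are canonicalized to coordinate order; ids are assigned from
#' coordinates when the name column is "." or absent.
#'
#' @param path path to a BEDPE file.
#' @param name library name.
#' @param cis_far_total the library's total cis-far unique valid pairs
#'   (from upstream QC; must be positive).
#' @param condition optional condition label.
#' @return a [loop_library()] object.
#' @export
read_bedpe <- function(path, name = basename(path), cis_far_total,
                       condition = NA_character_) {
  stopifnot_scalar_number(cis_far_total, "cis_far_total", min = 1)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) {
    stop("no loop records in ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 7L)) {
    stop("BEDPE rows need at least 7 columns (count column missing?)",
         call. = FALSE)
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  count_col <- ifelse(nf >= 8L, 8L, 7L)
  count <- suppressWarnings(as.numeric(mapply(function(f, i) f[i], fields, count_col)))
  if (any(is.na(count))) {
    stop("missing or non-numeric count column in BEDPE", call. = FALSE)
  }
  id <- ifelse(nf >= 8L, get(7L), NA_character_)
  id[id == "."] <- NA_character_
  chrom1 <- get(1L); chrom2 <- get(4L)
  inter <- chrom1 != chrom2
  if (any(inter)) {
    message(sprintf("read_bedpe: dropped %d inter-chromosomal loop(s)",
                    sum(inter)))
  }
  loops <- data.frame(
    chrom = chrom1,
    start1 = as.numeric(get(2L)), end1 = as.numeric(get(3L)),
    start2 = as.numeric(get(5L)), end2 = as.numeric(get(6L)),
    count = count, id = id, stringsAsFactors = FALSE
  )[!inter, , drop = FALSE]
  if (all(is.na(loops$id))) loops$id <- NULL else {
    miss <- is.na(loops$id)
    if (any(miss)) loops$id[miss] <- loop_key(loops[miss, , drop = FALSE])
  }
  loop_library(loops, name = name, cis_far_total = cis_far_total,
               condition = condition)
}

#' Write a loop library as 8-column BEDPE
#'
#' @param library a [loop_library()].
#' @param path output path.
#' @export
write_bedpe <- function(library, path) {
  l <- library$loops
  df <- data.frame(l$chrom, as.integer(l$start1), as.integer(l$end1),
                   l$chrom, as.integer(l$start2), as.integer(l$end2),
                   l$id, l$count)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models
#'
#' Gene models are a 4-column tab-separated table: gene_id, chrom, tss,
#' strand. The TSS is a single 0-based position; strand affects nothing
#' downstream beyond having been used to derive the TSS.
#'
#' @param path path to the gene-model table (header optional; detected by a
#'   non-numeric third field).
#' @return data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_gene_models <- function(path) {
  first <- utils::read.table(path, sep = "\t", nrows = 1,
                             stringsAsFactors = FALSE)
  header <- is.na(suppressWarnings(as.numeric(first[[3L]])))
  genes <- utils::read.table(path, sep = "\t", header = header,
                             stringsAsFactors = FALSE,
                             col.names = c("gene_id", "chrom", "tss", "strand"))
  if (any(is.na(genes$tss) | genes$tss < 0)) {
    stop("gene TSS positions must be nonnegative", call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  genes
}

#' Read a library metadata table
#'
#' Tab-separated columns: name, condition, cis_far_total. Used to carry the
#' per-library cis-far unique valid-pair totals alongside BEDPE files.
#'
#' @param path path to the metadata table.
#' @return data.frame with columns `name`, `condition`, `cis_far_total`.
#' @export
read_library_meta <- function(path) {
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  need <- c("name", "condition", "cis_far_total")
  if (!all(need %in% names(meta))) {
    stop("library metadata needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(meta$cis_far_total <= 0)) {
    stop("cis_far_total must be positive", call. = FALSE)
  }
  meta
}

#' Read an expression matrix
#'
#' Tab-separated gene x sample table with gene ids in the first column.
#'
#' @param path path to the table.
#' @return numeric matrix with gene ids as rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}
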