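#' Read a genome from a FASTA file
#'
#' Loads every record of a nucleotide FASTA file and returns the sequences
#' uppercased, in file order. Only the unambiguous DNA alphabet plus `N` is
#' accepted; anything else is a parse error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of class `met_genome`: one uppercase
#'   sequence per chromosome, names are the FASTA headers (first word).
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("genome FASTA not found: ", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) abort(paste0("empty FASTA: ", path))
  nms <- sub("\\s.*$", "", names(seqs))
  dup <- nms[duplicated(nms)]
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA header(s): ", paste(unique(dup), collapse = ", ")))
  }
  out <- toupper(as.character(seqs))
  names(out) <- nms
  bad <- vapply(out, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    abort(paste0("non-nucleotide characters (outside A/C/G/T/N) in record(s): ",
                 paste(nms[bad], collapse = ", ")))
  }
  structure(out, class = "met_genome")
}

#' Chromosome lengths of a genome
#'
#' @param genome A `met_genome` (named character vector of sequences).
#' @return Named integer vector of sequence lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  setNames(nchar(unclass(genome)), names(genome))
}

#' Read gene annotation from BED6 or GTF
#'
#' Produces one record per gene with a single transcription start site (TSS)
#' derived from the strand: the first base of the span for `+` genes, the last
#' base (`end - 1`) for `-` genes. All coordinates are 0-based half-open after
#' loading; GTF's 1-based closed coordinates are converted on read. Only
#' `gene`-type rows of a GTF are used (`dialect = "gtf-gene"`), with the gene
#' id taken from the `gene_id` attribute.
#'
#' @param path Path to a BED6 or GTF file.
#' @param dialect `"bed6"` or `"gtf-gene"`.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss` (0-based half-open; `tss` is a bp position).
#' @export
read_gene_annotation <- function(path, dialect = c("bed6", "gtf-gene")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  if (dialect == "bed6") {
    raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene_id", "score", "strand"),
                           col_types = "ciiccc", comment = "#", progress = FALSE)
    genes <- tibble(
      gene_id = raw$gene_id, chrom = raw$chrom,
      start = as.integer(raw$start), end = as.integer(raw$end),
      strand = raw$strand
    )
  } else {
    raw <- readr::read_tsv(path,
      col_names = c("chrom", "source", "feature", "start", "end", "score", "strand", "frame", "attributes"),
      col_types = "ccciicccc", comment = "#", progress = FALSE)
    raw <- raw[raw$feature == "gene", , drop = FALSE]
    if (nrow(raw) == 0) abort(paste0("no 'gene' feature rows in GTF: ", path))
    ids <- stringr::str_match(raw$attributes, 'gene_id[ =]+"?([^";]+)"?')[, 2]
    if (anyNA(ids)) abort("GTF gene row(s) without a gene_id attribute")
    genes <- tibble(
      gene_id = ids, chrom = raw$chrom,
      start = as.integer(raw$start) - 1L, end = as.integer(raw$end),
      strand = raw$strand
    )
  }
  bad_strand <- !genes$strand %in% c("+", "-")
  if (any(bad_strand)) {
    abort(paste0("unknown strand character for gene(s): ",
                 paste(genes$gene_id[bad_strand], collapse = ", ")))
  }
  bad_span <- genes$start >= genes$end
  if (any(bad_span)) {
    abort(paste0("start >= end for gene(s): ",
                 paste(genes$gene_id[bad_span], collapse = ", ")))
  }
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate gene_id(s): ", paste(dup, collapse = ", ")))
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tss <- as.integer(genes$tss)
  genes
}

#' Read motif count matrices
#'
#' Parses a motif collection into width-by-4 count matrices (columns A, C, G,
#' T). Supported dialects: JASPAR (`>id` header then four `A [ ... ]` rows),
#' TRANSFAC (`ID`/`PO`/numbered rows/`//`), and minimal MEME text
#' (`MOTIF` + `letter-probability matrix` blocks; probabilities are scaled by
#' `nsites`, default 20, to pseudo-counts). Counts are kept exactly as
#' printed. Duplicate motif ids are disambiguated with a `_2`, `_3`, ...
#' suffix and a message.
#'
#' @param path Path to the motif file.
#' @param dialect One of `"jaspar"`, `"transfac"`, `"meme-minimal"`.
#' @return A named list of numeric matrices (class `met_motifs`); each matrix
#'   has one row per motif position and columns `A`, `C`, `G`, `T`.
#' @export
read_motifs <- function(path, dialect = c("jaspar", "transfac", "meme-minimal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("motif file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  mats <- switch(dialect,
    "jaspar" = parse_jaspar(lines, path),
    "transfac" = parse_transfac(lines, path),
    "meme-minimal" = parse_meme_minimal(lines, path)
  )
  if (length(mats) == 0) abort(paste0("no motifs found in ", path))
  ids <- names(mats)
  if (anyDuplicated(ids)) {
    for (id in unique(ids[duplicated(ids)])) {
      idx <- which(ids == id)
      for (j in seq_along(idx)[-1]) {
        ids[idx[j]] <- paste0(id, "_", j)
      }
      inform(paste0("motif id collision for '", id, "': suffixed duplicates"))
    }
    names(mats) <- ids
  }
  structure(mats, class = "met_motifs")
}

validate_motif_matrix <- function(mat, id) {
  if (nrow(mat) < 1) abort(paste0("motif ", id, ": zero width"))
  if (any(!is.finite(mat)) || any(mat < 0)) {
    abort(paste0("motif ", id, ": negative or non-finite counts"))
  }
  zero <- which(rowSums(mat) == 0)
  if (length(zero) > 0) {
    abort(paste0("motif ", id, ": position(s) ", paste(zero, collapse = ", "),
                 " have zero total count"))
  }
  colnames(mat) <- c("A", "C", "G", "T")
  mat
}

parse_jaspar <- function(lines, path) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) abort(paste0("no JASPAR records ('>' headers) in ", path))
  ends <- c(hdr[-1] - 1L, length(lines))
  mats <- list()
  for (i in seq_along(hdr)) {
    id <- stringr::str_split(sub("^>\\s*", "", lines[hdr[i]]), "\\s+")[[1]][1]
    body <- lines[seq(hdr[i] + 1L, ends[i])]
    body <- body[nzchar(trimws(body))]
    if (length(body) != 4) {
      abort(paste0("motif ", id, ": expected 4 base rows, found ", length(body)))
    }
    rows <- lapply(body, function(ln) {
      nums <- stringr::str_extract_all(ln, "-?[0-9]*\\.?[0-9]+")[[1]]
      as.numeric(nums)
    })
    widths <- lengths(rows)
    if (length(unique(widths)) != 1) {
      abort(paste0("motif ", id, ": ragged matrix rows (widths ",
                   paste(widths, collapse = "/"), ")"))
    }
    base_order <- toupper(substr(trimws(body), 1, 1))
    mat <- do.call(cbind, rows)  # width x 4, columns in file row order
    if (all(sort(base_order) == c("A", "C", "G", "T"))) {
      mat <- mat[, match(c("A", "C", "G", "T"), base_order), drop = FALSE]
    }
    mats <- c(mats, setNames(list(validate_motif_matrix(mat, id)), id))
  }
  mats
}

parse_transfac <- function(lines, path) {
  mats <- list()
  id <- NULL
  rows <- NULL
  for (ln in lines) {
    if (grepl("^(ID|NA)\\s", ln)) {
      cand <- trimws(sub("^(ID|NA)\\s+", "", ln))
      if (is.null(id) || grepl("^ID", ln)) id <- cand
    } else if (grepl("^P0|^PO", ln)) {
      rows <- list()
    } else if (grepl("^[0-9]+\\s", ln) && !is.null(rows)) {
      nums <- stringr::str_split(trimws(ln), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(nums[2:5]))
      if (anyNA(vals)) abort(paste0("motif ", id, ": malformed count row '", ln, "'"))
      rows[[length(rows) + 1L]] <- vals
    } else if (grepl("^//", ln)) {
      if (!is.null(rows) && length(rows) > 0) {
        if (is.null(id)) abort(paste0("TRANSFAC record without ID in ", path))
        mats <- c(mats, setNames(list(validate_motif_matrix(do.call(rbind, rows), id)), id))
      }
      id <- NULL
      rows <- NULL
    }
  }
  if (!is.null(rows) && length(rows) > 0 && !is.null(id)) {
    mats <- c(mats, setNames(list(validate_motif_matrix(do.call(rbind, rows), id)), id))
  }
  mats
}

parse_meme_minimal <- function(lines, path) {
  mats <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF\\s", lines[i])) {
      id <- stringr::str_split(trimws(sub("^MOTIF\\s+", "", lines[i])), "\\s+")[[1]][1]
      j <- i + 1L
      while (j <= length(lines) && !grepl("letter-probability matrix", lines[j])) j <- j + 1L
      if (j > length(lines)) abort(paste0("motif ", id, ": no letter-probability matrix"))
      nsites <- stringr::str_match(lines[j], "nsites=\\s*([0-9]+)")[, 2]
      nsites <- if (is.na(nsites)) 20 else as.numeric(nsites)
      rows <- list()
      j <- j + 1L
      while (j <= length(lines) && grepl("^\\s*[0-9.eE+-]", lines[j]) && nzchar(trimws(lines[j]))) {
        vals <- suppressWarnings(as.numeric(stringr::str_split(trimws(lines[j]), "\\s+")[[1]]))
        if (length(vals) != 4 || anyNA(vals)) {
          abort(paste0("motif ", id, ": malformed probability row '", lines[j], "'"))
        }
        rows[[length(rows) + 1L]] <- vals * nsites
        j <- j + 1L
      }
      mats <- c(mats, setNames(list(validate_motif_matrix(do.call(rbind, rows), id)), id))
      i <- j
    } else {
      i <- i + 1L
    }
  }
  mats
}

#' Read a bedGraph signal track
#'
#' Loads a 4-column bedGraph (chrom, start, end, value; 0-based half-open)
#' into a tibble sorted by (chrom, start). Overlapping intervals within a
#' chromosome and non-finite values are rejected with the offending line
#' numbers.
#'
#' @param path Path to a bedGraph file.
#' @return A tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_signal_track <- function(path) {
  if (!file.exists(path)) abort(paste0("signal track not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- stringr::str_split(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 4)) {
    abort(paste0("bedGraph line(s) without 4 columns: line ",
                 paste(lineno[nf != 4], collapse = ", ")))
  }
  m <- do.call(rbind, fields)
  value <- suppressWarnings(as.numeric(m[, 4]))
  bad <- !is.finite(value)
  if (any(bad)) {
    abort(paste0("malformed or non-finite value at line ",
                 paste(lineno[bad], collapse = ", ")))
  }
  track <- tibble(
    chrom = m[, 1],
    start = as.integer(m[, 2]),
    end = as.integer(m[, 3]),
    value = value,
    .line = lineno
  )
  ord <- order(track$chrom, track$start)
  track <- track[ord, ]
  same <- track$chrom[-1] == track$chrom[-nrow(track)]
  if (nrow(track) > 1) {
    ovl <- which(same & track$start[-1] < track$end[-nrow(track)])
    if (length(ovl) > 0) {
      i <- ovl[1]
      abort(paste0("overlapping intervals at lines ", track$.line[i], " and ",
                   track$.line[i + 1]))
    }
  }
  track$.line <- NULL
  track
}

#' Read a gene id list
#'
#' One gene id per line; blank lines and `#` comments ignored.
#'
#' @param path Path to a plain-text file.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(paste0("gene list not found: ", path))
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Write enrichment reports
#'
#' Writes a summary TSV (one row per user set x configuration, with the count
#' and fraction of significant features and the names of the top features)
#' and one detail TSV per configuration. Detail columns: feature id,
#' target-set size, overlap count, p-value (scientific, 3 significant
#' digits), -log10 p, and the comma-separated overlap gene list; rows are
#' sorted ascending by p.
#'
#' @param results A tibble of enrichment results as produced by
#'   [run_configuration()] (class `met_enrichment`), or a list of them.
#' @param out_dir Output directory (created if missing).
#' @param max_p Significance threshold used for the summary's
#'   significant-feature counts and top-feature names (default 0.05).
#' @param top_n Number of top feature names listed in the summary (default 5).
#' @return Invisibly, a character vector of the files written.
#' @export
write_reports <- function(results, out_dir, max_p = 0.05, top_n = 5) {
  if (is.null(results)) abort("results must be non-null")
  if (inherits(results, "data.frame")) results <- list(results)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  files <- character(0)
  summary_rows <- list()
  for (res in results) {
    fp <- res$fingerprint[1]
    detail <- res |>
      arrange(.data$p_value, .data$feature_id) |>
      mutate(
        p_value_fmt = formatC(.data$p_value, format = "e", digits = 2),
        neg_log10_p = round(-log10(.data$p_value), 6)
      )
    out <- tibble(
      feature_id = detail$feature_id,
      user_set = detail$user_set,
      target_size = detail$target_size,
      user_size = detail$user_size,
      overlap = detail$overlap,
      p_value = detail$p_value_fmt,
      neg_log10_p = detail$neg_log10_p,
      overlap_genes = vapply(detail$overlap_genes, paste, character(1), collapse = ",")
    )
    f <- file.path(out_dir, paste0("details_", fp, ".tsv"))
    readr::write_tsv(out, f, progress = FALSE)
    files <- c(files, f)
    for (us in unique(res$user_set)) {
      sub <- detail |> filter(.data$user_set == us)
      sig <- sub |> filter(.data$p_value <= max_p)
      summary_rows[[length(summary_rows) + 1L]] <- tibble(
        user_set = us,
        fingerprint = fp,
        n_tests = nrow(sub),
        n_significant = nrow(sig),
        frac_significant = if (nrow(sub) > 0) nrow(sig) / nrow(sub) else 0,
        top_features = paste(head(sig$feature_id, top_n), collapse = ",")
      )
    }
  }
  f <- file.path(out_dir, "summary.tsv")
  readr::write_tsv(bind_rows(summary_rows), f, progress = FALSE)
  files <- c(files, f)
  invisible(files)
}
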