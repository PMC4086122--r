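#' Seed-deterministic synthetic inputs
#'
#' These generators build fully synthetic inputs — genome, gene annotation,
#' motifs with planted consensus sites, accessibility tracks and user gene
#' sets — with known ground truth, so every pipeline stage and the
#' end-to-end method can be exercised without external data. All randomness
#' flows from a single master seed through named substreams (genome,
#' annotation, motif, planting, accessibility), so each component is
#' reproducible on its own.
#'
#' @name synthetic_fixtures
NULL

# independent substream: derive a 32-bit sub-seed from (seed, label)
substream_seed <- function(seed, label) {
  h <- digest::digest(list(as.integer(seed), label), algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

with_substream <- function(seed, label, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  force(code)
}

#' Generate a random genome
#'
#' I.i.d. bases with `P(G) + P(C) = gc_target` (split evenly within each
#' pair), deterministic per seed.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (recycled).
#' @param gc_target Target G+C fraction in (0, 1) (default 0.41).
#' @param seed Master seed.
#' @return A `met_genome`.
#' @export
make_genome <- function(n_chrom = 1L, chrom_length = 1e6, gc_target = 0.41,
                        seed = 1L) {
  if (gc_target <= 0 || gc_target >= 1) abort("gc_target must be in (0, 1)")
  chrom_length <- rep_len(as.integer(chrom_length), n_chrom)
  if (any(chrom_length < 1000)) abort("chromosome lengths must be >= 1000 bp")
  probs <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
             G = gc_target / 2, T = (1 - gc_target) / 2)
  seqs <- with_substream(seed, "genome", {
    vapply(seq_len(n_chrom), function(i) {
      paste(sample(names(probs), chrom_length[i], replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  structure(seqs, class = "met_genome")
}

#' Generate a random gene annotation
#'
#' Places non-overlapping genes uniformly with a minimum inter-gene spacing,
#' random strands, deterministic per seed.
#'
#' @param genome A `met_genome`.
#' @param n_genes Number of genes.
#' @param gene_length Gene body length in bp (default 1000).
#' @param min_spacing Minimum gap between gene bodies in bp (default 2000).
#' @param seed Master seed.
#' @return A gene annotation tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`).
#' @export
make_annotation <- function(genome, n_genes = 200L, gene_length = 1000L,
                            min_spacing = 2000L, seed = 1L) {
  lens <- chrom_lengths(genome)
  n_genes <- as.integer(n_genes)
  slot <- as.integer(gene_length + min_spacing)
  # per-chromosome capacity under the spacing constraint
  cap <- pmax((lens - min_spacing) %/% slot, 0L)
  if (sum(cap) < n_genes) {
    abort(paste0("cannot place ", n_genes, " genes with >= ", min_spacing,
                 " bp spacing on this genome (capacity ", sum(cap), ")"))
  }
  with_substream(seed, "annotation", {
    # distribute genes over chromosomes proportional to capacity
    alloc <- integer(length(lens))
    remaining <- n_genes
    for (i in seq_along(lens)) {
      take <- min(cap[i], remaining)
      alloc[i] <- take
      remaining <- remaining - take
    }
    rows <- list()
    gid <- 1L
    for (i in seq_along(lens)) {
      if (alloc[i] == 0) next
      # draw gene slots on a spacing-preserving grid
      slots <- sort(sample.int(cap[i], alloc[i]))
      start <- as.integer((slots - 1L) * slot + min_spacing)
      strand <- sample(c("+", "-"), alloc[i], replace = TRUE)
      rows[[i]] <- tibble(
        gene_id = sprintf("g%04d", seq.int(gid, gid + alloc[i] - 1L)),
        chrom = names(lens)[i],
        start = start, end = start + as.integer(gene_length),
        strand = strand)
      gid <- gid + alloc[i]
    }
    genes <- bind_rows(rows)
    genes$tss <- as.integer(ifelse(genes$strand == "+", genes$start, genes$end - 1L))
    genes
  })
}

#' Generate a random sharp motif
#'
#' A count matrix with a dominant consensus base per position, giving a
#' high-information motif whose consensus string is unambiguous.
#'
#' @param width Motif width (default 8).
#' @param counts_total Total count per position (default 100).
#' @param consensus_fraction Fraction of counts on the consensus base
#'   (default 0.85).
#' @param seed Master seed.
#' @param label Substream label (vary to draw independent motifs).
#' @return A width x 4 count matrix (columns A, C, G, T).
#' @export
make_motif <- function(width = 8L, counts_total = 100, consensus_fraction = 0.85,
                       seed = 1L, label = "motif") {
  with_substream(seed, label, {
    cons <- sample(1:4, width, replace = TRUE)
    mat <- matrix(counts_total * (1 - consensus_fraction) / 3,
                  nrow = width, ncol = 4)
    mat[cbind(seq_len(width), cons)] <- counts_total * consensus_fraction
    colnames(mat) <- c("A", "C", "G", "T")
    mat
  })
}

# decoys with the same per-column composition: random row (position)
# permutations of the planted matrix, never the identity
permute_motif_rows <- function(mat, n_decoys, seed) {
  with_substream(seed, "decoys", {
    lapply(seq_len(n_decoys), function(i) {
      repeat {
        perm <- sample(nrow(mat))
        if (!all(perm == seq_len(nrow(mat)))) break
      }
      m <- mat[perm, , drop = FALSE]
      colnames(m) <- colnames(mat)
      m
    })
  })
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Plant motif consensus sites upstream of selected genes
#'
#' Writes copies of the motif consensus (arg-max base per position) at
#' random positions within each selected gene's upstream span, on a random
#' strand, avoiding gene bodies. Every edit is recorded in a site log; the
#' genome differs from the input only at logged positions.
#'
#' @param genome A `met_genome`.
#' @param genes Gene annotation tibble.
#' @param motif A count matrix or `met_motif` whose consensus is planted.
#' @param gene_ids Genes receiving sites.
#' @param upstream_bp Width of the upstream span to plant in (default 2000).
#' @param sites_per_gene Sites per selected gene (default 3).
#' @param seed Master seed.
#' @return A list: `genome` (modified), `site_log` (tibble `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `site`).
#' @export
plant_sites <- function(genome, genes, motif, gene_ids, upstream_bp = 2000L,
                        sites_per_gene = 3L, seed = 1L) {
  cons <- motif_consensus(motif)
  W <- nchar(cons)
  if (W > upstream_bp) abort("motif consensus longer than the upstream span")
  lens <- chrom_lengths(genome)
  sel <- genes[genes$gene_id %in% gene_ids, ]
  if (nrow(sel) != length(unique(gene_ids))) {
    abort("gene_ids contains genes absent from the annotation")
  }
  bodies <- genes[, c("chrom", "start", "end")]
  seqs <- as.list(unclass(genome))
  log_rows <- list()
  with_substream(seed, "planting", {
    for (i in seq_len(nrow(sel))) {
      g <- sel[i, ]
      if (g$strand == "+") {
        span <- c(max(0L, g$tss - as.integer(upstream_bp)), g$tss)
      } else {
        span <- c(g$tss + 1L, min(unname(lens[g$chrom]), g$tss + 1L + as.integer(upstream_bp)))
      }
      if (span[2] - span[1] < W) abort(paste0("upstream span of ", g$gene_id, " too small"))
      for (s in seq_len(sites_per_gene)) {
        placed <- FALSE
        for (attempt in 1:100) {
          pos <- span[1] + sample.int(span[2] - span[1] - W + 1L, 1L) - 1L
          in_body <- any(bodies$chrom == g$chrom & pos < bodies$end & (pos + W) > bodies$start)
          if (!in_body) { placed <- TRUE; break }
        }
        if (!placed) {
          abort(paste0("could not place a site for ", g$gene_id,
                       " outside gene bodies after 100 draws"))
        }
        strand <- sample(c("+", "-"), 1L)
        site <- if (strand == "+") cons else revcomp(cons)
        substr(seqs[[g$chrom]], pos + 1L, pos + W) <- site
        log_rows[[length(log_rows) + 1L]] <- tibble(
          gene_id = g$gene_id, chrom = g$chrom, start = pos, end = pos + W,
          strand = strand, site = site)
      }
    }
  })
  list(genome = structure(unlist(seqs), class = "met_genome"),
       site_log = bind_rows(log_rows))
}

#' Generate a synthetic accessibility track
#'
#' Emulates a DNase-hypersensitivity profile: gamma-distributed high signal
#' (mean `10 * background_level`, or mean 10 when the background is 0) over
#' the open regions, flat background elsewhere. Deterministic per seed.
#'
#' @param genome A `met_genome` (for chromosome extents).
#' @param open_regions Tibble `chrom`, `start`, `end` of open intervals.
#' @param background_level Signal outside open regions (default 1).
#' @param seed Master seed.
#' @return A signal tibble (`chrom`, `start`, `end`, `value`) with
#'   non-overlapping sorted intervals.
#' @export
make_accessibility <- function(genome, open_regions, background_level = 1,
                               seed = 1L) {
  lens <- chrom_lengths(genome)
  oob <- open_regions$end > lens[open_regions$chrom] | open_regions$start < 0
  if (any(oob)) abort("open region(s) outside the genome")
  open_mean <- if (background_level > 0) 10 * background_level else 10
  rows <- list()
  with_substream(seed, "accessibility", {
    for (chrom in names(lens)) {
      op <- open_regions[open_regions$chrom == chrom, ]
      op <- merge_intervals(op[order(op$start), ])
      pos <- 0L
      L <- unname(lens[chrom])
      add <- function(s, e, v) {
        rows[[length(rows) + 1L]] <<- tibble(chrom = chrom, start = s, end = e, value = v)
      }
      for (i in seq_len(nrow(op))) {
        if (op$start[i] > pos) add(pos, op$start[i], background_level)
        add(op$start[i], op$end[i],
            round(rgamma(1, shape = 4, scale = open_mean / 4), 4))
        pos <- op$end[i]
      }
      if (pos < L) add(pos, L, background_level)
    }
  })
  bind_rows(rows)
}

# union of possibly-overlapping sorted intervals on one chromosome
merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  start <- iv$start
  end <- iv$end
  out_s <- start[1]
  out_e <- end[1]
  for (i in 2:nrow(iv)) {
    if (start[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], end[i])
    } else {
      out_s <- c(out_s, start[i])
      out_e <- c(out_e, end[i])
    }
  }
  tibble(chrom = iv$chrom[1], start = out_s, end = out_e)
}

#' Compose a full planted-motif benchmark case
#'
#' Builds a genome, annotation, one planted high-information motif plus
#' `n_decoys` information-matched decoys (row permutations of the planted
#' matrix, so recovery tests discrimination rather than motif strength),
#' plants consensus sites upstream of a random subset of genes, and records
#' the ground truth. An accessibility track covering the planted upstream
#' spans is included.
#'
#' @param n_genes Number of genes (default 200).
#' @param planted_fraction Fraction of genes receiving sites (default 0.25).
#' @param n_decoys Number of decoy motifs (default 19).
#' @param sites_per_gene Planted sites per selected gene (default 3).
#' @param upstream_bp Planting span upstream of the TSS (default 2000).
#' @param chrom_length Genome length in bp (default 1e6).
#' @param seed Master seed.
#' @return A `met_benchmark` list: `genome`, `genes`, `motifs`
#'   (`met_motifs`, planted first), `truth` (planted motif id, planted gene
#'   ids, parameters), `access`, `site_log`, `seed`.
#' @export
make_benchmark_case <- function(n_genes = 200L, planted_fraction = 0.25,
                                n_decoys = 19L, sites_per_gene = 3L,
                                upstream_bp = 2000L, chrom_length = 1e6,
                                seed = 1L) {
  genome <- make_genome(n_chrom = 1L, chrom_length = chrom_length, seed = seed)
  genes <- make_annotation(genome, n_genes = n_genes, seed = seed)
  planted_mat <- make_motif(seed = seed, label = "motif")
  decoys <- permute_motif_rows(planted_mat, n_decoys, seed)
  motifs <- c(list(planted = planted_mat),
              setNames(decoys, paste0("decoy", sprintf("%02d", seq_len(n_decoys)))))
  class(motifs) <- "met_motifs"
  n_planted <- round(planted_fraction * n_genes)
  planted_genes <- with_substream(seed, "planted_genes", {
    sort(sample(genes$gene_id, n_planted))
  })
  planted <- plant_sites(genome, genes, planted_mat, planted_genes,
                         upstream_bp = upstream_bp,
                         sites_per_gene = sites_per_gene, seed = seed)
  open <- genes[genes$gene_id %in% planted_genes, ] |>
    mutate(
      start = as.integer(ifelse(.data$strand == "+",
                                pmax(0L, .data$tss - .env$upstream_bp), .data$tss + 1L)),
      end = as.integer(ifelse(.data$strand == "+", .data$tss,
                              .data$tss + 1L + .env$upstream_bp))) |>
    select("chrom", "start", "end") |>
    arrange(.data$start)
  access <- make_accessibility(planted$genome, open, seed = seed)
  structure(list(
    genome = planted$genome, genes = genes, motifs = motifs,
    truth = list(planted_motif = "planted", planted_genes = planted_genes,
                 sites_per_gene = sites_per_gene, upstream_bp = upstream_bp),
    access = access, site_log = planted$site_log, seed = seed),
    class = "met_benchmark")
}

#' Write a benchmark case as standard files
#'
#' Emits the case as FASTA, BED6, JASPAR matrices, bedGraph and gene-list
#' text files so fixtures double as CLI integration inputs.
#'
#' @param case A `met_benchmark` from [make_benchmark_case()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named vector of the files written.
#' @export
write_benchmark_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- c(genome = file.path(dir, "genome.fa"),
         genes = file.path(dir, "genes.bed"),
         motifs = file.path(dir, "motifs.jaspar"),
         access = file.path(dir, "access.bedgraph"),
         user_set = file.path(dir, "user_set.txt"))
  writeLines(paste0(">", names(case$genome), "\n", unclass(case$genome)), f["genome"])
  readr::write_tsv(case$genes |>
    mutate(score = 0L) |>
    select("chrom", "start", "end", "gene_id", "score", "strand"),
    f["genes"], col_names = FALSE, progress = FALSE)
  con <- file(f["motifs"], "w")
  for (id in names(case$motifs)) {
    mat <- case$motifs[[id]]
    writeLines(paste0(">", id), con)
    for (b in 1:4) {
      writeLines(paste0(c("A", "C", "G", "T")[b], " [ ",
                        paste(format(mat[, b], trim = TRUE), collapse = " "), " ]"), con)
    }
  }
  close(con)
  readr::write_tsv(case$access, f["access"], col_names = FALSE, progress = FALSE)
  writeLines(case$truth$planted_genes, f["user_set"])
  invisible(f)
}
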