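# canonical float formatting for all text writers (6 significant digits by
# default; tests compare numerically, not textually)
fmt_num <- function(x, precision = 6L) {
  formatC(x, digits = precision, format = "g")
}

parse_error <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

#' Write / read a per-population allele-frequency table
#'
#' Tab-separated layout with header `snp_id<TAB>pop1<TAB>pop2...` and one
#' row per SNP. Population sizes travel in a sidecar file (default
#' `<path>.sizes`) with one `population<TAB>size` line per population, so
#' the reader can rebuild the full [pop_structure()].
#'
#' @param freqs a [freq_table()].
#' @param structure the matching [pop_structure()].
#' @param path output TSV path; the sizes sidecar is written next to it.
#' @param sizes_path sizes file path.
#' @param precision significant digits for frequencies.
#' @return `write_freq_table()` returns `path` invisibly;
#'   `read_freq_table()` returns `list(freqs, structure)`.
#' @export
write_freq_table <- function(freqs, structure, path,
                             sizes_path = paste0(path, ".sizes"),
                             precision = 10L) {
  check_pair(structure, freqs)
  header <- paste(c("snp_id", structure$labels), collapse = "\t")
  rows <- vapply(seq_len(freqs$n_snps), function(m) {
    paste(c(freqs$snp_ids[m], fmt_num(freqs$freqs[, m], precision)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  writeLines(paste(structure$labels, structure$sizes, sep = "\t"),
             sizes_path)
  invisible(path)
}

#' @rdname write_freq_table
#' @export
read_freq_table <- function(path, sizes_path = paste0(path, ".sizes")) {
  lines <- readLines(path)
  if (length(lines) < 2L) {
    parse_error(path, 1L, "expected a header line and at least one SNP row")
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "snp_id") {
    parse_error(path, 1L, "header must be 'snp_id<TAB>pop1<TAB>...'")
  }
  pops <- header[-1]
  K <- length(pops)
  snp_ids <- character(length(lines) - 1L)
  f <- matrix(NA_real_, K, length(lines) - 1L)
  for (i in seq_along(snp_ids)) {
    fields <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(fields) != K + 1L) {
      parse_error(path, i + 1L,
                  sprintf("expected %d fields, found %d", K + 1L,
                          length(fields)))
    }
    snp_ids[i] <- fields[1]
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(vals)) {
      parse_error(path, i + 1L, "non-numeric allele frequency")
    }
    if (any(vals < 0) || any(vals > 1)) {
      parse_error(path, i + 1L,
                  sprintf("allele frequency out of [0, 1]: %s",
                          fields[-1][which(vals < 0 | vals > 1)[1]]))
    }
    f[, i] <- vals
  }
  if (anyDuplicated(snp_ids)) {
    dup <- snp_ids[duplicated(snp_ids)][1]
    parse_error(path, which(snp_ids == dup)[2] + 1L,
                sprintf("duplicate SNP id '%s'", dup))
  }
  if (!file.exists(sizes_path)) {
    stop(sprintf("population sizes file not found: %s", sizes_path),
         call. = FALSE)
  }
  sz <- utils::read.table(sizes_path, sep = "\t", header = FALSE,
                          col.names = c("population", "size"),
                          stringsAsFactors = FALSE)
  if (!setequal(sz$population, pops)) {
    stop(sprintf("%s: populations do not match the header of %s",
                 sizes_path, path), call. = FALSE)
  }
  sizes <- sz$size[match(pops, sz$population)]
  ps <- pop_structure(sizes, pops)
  list(freqs = freq_table(f, snp_ids = snp_ids, pop_labels = pops),
       structure = ps)
}

#' Read a sample-to-population labels file
#'
#' Two tab-separated columns, `sample_id<TAB>population`, no header.
#' Samples must appear in population-contiguous blocks; a file whose
#' populations interleave is rejected with a message instructing to sort.
#'
#' @param path labels TSV path.
#' @return `list(structure, sample_ids)`.
#' @export
read_labels <- function(path) {
  lab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("sample_id", "population"),
                           stringsAsFactors = FALSE)
  r <- rle(lab$population)
  if (anyDuplicated(r$values)) {
    stop(sprintf(
      "%s: samples are not grouped by population; sort the file so each population forms one contiguous block",
      path), call. = FALSE)
  }
  list(structure = pop_structure(r$lengths, r$values),
       sample_ids = lab$sample_id)
}

#' @rdname read_labels
#' @param structure a [pop_structure()].
#' @param sample_ids sample identifiers ordered by population block.
#' @export
write_labels <- function(structure, path,
                         sample_ids = default_sample_ids(structure)) {
  writeLines(paste(sample_ids, structure$labels[structure$membership],
                   sep = "\t"), path)
  invisible(path)
}

#' Read genotypes from plain-text formats
#'
#' Two dialects are supported:
#' * `tsv` — samples in rows: header `sample_id<TAB>snp1<TAB>...`, one row
#'   of 0/1/2 counts per sample.
#' * `traw` — PLINK transposed raw text, SNPs in rows: header
#'   `CHR SNP (C)M POS COUNTED ALT <sample...>` (tab-separated); the
#'   COUNTED column names the coded allele whose copies are counted.
#'
#' Missing genotypes (`NA`) are rejected — the relationship-matrix model
#' assumes complete data. Samples are reordered to match the labels file,
#' which must be block-contiguous by population.
#'
#' @param path genotype file.
#' @param labels_path sample-to-population labels file, see
#'   [read_labels()].
#' @param dialect `"tsv"` or `"traw"`.
#' @return `list(genotypes, structure)`; for traw input the genotype
#'   matrix carries an `"alleles"` attribute with the COUNTED/ALT columns.
#' @export
read_genotypes <- function(path, labels_path, dialect = c("tsv", "traw")) {
  dialect <- match.arg(dialect)
  lab <- read_labels(labels_path)
  if (dialect == "tsv") {
    dat <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             na.strings = "NA")
    sample_ids <- as.character(dat[[1]])
    X <- as.matrix(dat[, -1, drop = FALSE])
    snp_ids <- colnames(X)
    alleles <- NULL
  } else {
    dat <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             na.strings = "NA")
    meta_cols <- c("CHR", "SNP", "(C)M", "POS", "COUNTED", "ALT")
    if (!all(meta_cols %in% colnames(dat)[seq_len(6)])) {
      stop(sprintf(
        "%s: not a traw file (expected columns CHR SNP (C)M POS COUNTED ALT)",
        path), call. = FALSE)
    }
    snp_ids <- as.character(dat$SNP)
    sample_ids <- colnames(dat)[-seq_len(6)]
    X <- t(as.matrix(dat[, -seq_len(6), drop = FALSE]))
    colnames(X) <- snp_ids
    alleles <- data.frame(snp_id = snp_ids, counted = dat$COUNTED,
                          alt = dat$ALT, stringsAsFactors = FALSE)
  }
  if (anyNA(X)) {
    stop(sprintf("%s: missing genotypes (NA) are not supported", path),
         call. = FALSE)
  }
  if (!setequal(sample_ids, lab$sample_ids)) {
    stop(sprintf("%s: sample ids do not match the labels file", path),
         call. = FALSE)
  }
  X <- X[match(lab$sample_ids, sample_ids), , drop = FALSE]
  gm <- genotype_matrix(X, sample_ids = lab$sample_ids, snp_ids = snp_ids)
  if (!is.null(alleles)) attr(gm, "alleles") <- alleles
  list(genotypes = gm, structure = lab$structure)
}

#' @rdname read_genotypes
#' @param genotypes a [genotype_matrix()].
#' @export
write_genotypes <- function(genotypes, path) {
  header <- paste(c("sample_id", genotypes$snp_ids), collapse = "\t")
  rows <- vapply(seq_len(nrow(genotypes$values)), function(i) {
    paste(c(genotypes$sample_ids[i], genotypes$values[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write / read a square relationship matrix
#'
#' Plain-text square matrix with a header row of sample ids (GCTA-like
#' convention); readable back with the kind supplied by the caller.
#'
#' @param matrix a [relationship_matrix()].
#' @param path TSV path.
#' @param precision significant digits.
#' @export
write_relationship_matrix <- function(matrix, path, precision = 10L) {
  V <- matrix$values
  header <- paste(matrix$sample_ids, collapse = "\t")
  rows <- vapply(seq_len(nrow(V)), function(i) {
    paste(fmt_num(V[i, ], precision), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_relationship_matrix
#' @param kind matrix kind tag for the reader.
#' @param structure optional [pop_structure()] to attach.
#' @export
read_relationship_matrix <- function(path,
                                     kind = c("empirical-GRM",
                                              "theoretical-EGRM"),
                                     structure = NULL) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  n <- length(ids)
  if (length(lines) != n + 1L) {
    parse_error(path, length(lines),
                sprintf("expected %d matrix rows, found %d", n,
                        length(lines) - 1L))
  }
  V <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    vals <- suppressWarnings(
      as.numeric(strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]))
    if (length(vals) != n || anyNA(vals)) {
      parse_error(path, i + 1L, "malformed matrix row")
    }
    V[i, ] <- vals
  }
  relationship_matrix(V, kind = kind, structure = structure,
                      sample_ids = ids, sym_tol = 1e-6)
}

#' Write eigenvalues and eigenvectors in eigenval/eigenvec layout
#'
#' `prefix.eigenval` holds one eigenvalue per line; `prefix.eigenvec`
#' holds per-sample rows `sample_id population PC1 PC2 ...`
#' (tab-separated, with header). With `scaled = TRUE` coordinates are
#' multiplied by the square roots of their eigenvalues, the scaling used
#' for representative-point plots.
#'
#' @param result an `eigen_result` or [structural_spectrum()].
#' @param prefix output path prefix.
#' @param structure a [pop_structure()] supplying population labels.
#' @param topk number of PCs to write (default all available).
#' @param scaled multiply coordinates by `sqrt(lambda)`.
#' @param precision significant digits.
#' @return The two file paths, invisibly.
#' @export
write_eigen <- function(result, prefix, structure, topk = NULL,
                        scaled = FALSE, precision = 6L) {
  values <- result$values
  vectors <- result$vectors
  if (is.null(topk)) topk <- ncol(vectors)
  topk <- as.integer(topk)
  if (topk < 1L || topk > ncol(vectors)) {
    stop(sprintf("topk must be between 1 and %d", ncol(vectors)),
         call. = FALSE)
  }
  coords <- vectors[, seq_len(topk), drop = FALSE]
  if (scaled) {
    coords <- sweep(coords, 2L, sqrt(pmax(values[seq_len(topk)], 0)), "*")
  }
  val_path <- paste0(prefix, ".eigenval")
  vec_path <- paste0(prefix, ".eigenvec")
  writeLines(fmt_num(values, precision), val_path)
  header <- paste(c("sample_id", "population",
                    sprintf("PC%d", seq_len(topk))), collapse = "\t")
  pops <- structure$labels[structure$membership]
  rows <- vapply(seq_len(nrow(coords)), function(i) {
    paste(c(rownames(vectors)[i], pops[i], fmt_num(coords[i, ], precision)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), vec_path)
  invisible(c(val_path, vec_path))
}

#' Write a divergence report as key-value TSV
#'
#' @param report a [divergence_report()].
#' @param path output path.
#' @param precision significant digits.
#' @export
write_divergence_report <- function(report, path, precision = 6L) {
  keys <- c("sigma_B2", "sigma_W2", "f_pc", "f_pc_star", "d2", "k_pcs",
            "n_snps", "mode")
  vals <- vapply(keys, function(k) {
    v <- report[[k]]
    if (is.numeric(v)) fmt_num(v, precision) else as.character(v)
  }, character(1))
  writeLines(paste(keys, vals, sep = "\t"), path)
  invisible(path)
}
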