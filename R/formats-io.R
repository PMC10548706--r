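#' Read a FASTA file into a tibble
#'
#' One row per record; multi-line sequences are concatenated and input order
#' is preserved. Protein records may use the 20 standard residues plus `X`
#' (any other ambiguity code is rejected so that downstream identity values
#' are deterministic); CDS records must be non-empty `ACGT` strings.
#'
#' @param path Path to a FASTA file.
#' @param kind `"protein"`, `"cds"`, or `"auto"` (default) to infer from the
#'   alphabet of the first record.
#' @return Tibble with columns `id`, `description`, `sequence`, `kind`.
#' @export
read_fasta <- function(path, kind = c("auto", "protein", "cds")) {
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) NULL)
  if (is.null(set) || length(set) == 0) {
    warn(paste0("empty FASTA file: ", path))
    return(tibble::tibble(id = character(), description = character(),
                          sequence = character(), kind = character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate FASTA ids: ", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  if (kind == "auto") {
    kind <- if (grepl("^[ACGTN]*$", seqs[[1]])) "cds" else "protein"
  }
  if (kind == "protein") {
    bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", seqs)
    if (any(bad)) {
      abort(paste0("non-standard protein residues in: ",
                   paste(ids[bad], collapse = ", "),
                   " (only the 20 amino acids plus X are accepted)"))
    }
  } else {
    bad <- !grepl("^[ACGT]+$", seqs)
    if (any(bad)) {
      abort(paste0("invalid CDS records (must be non-empty ACGT): ",
                   paste(ids[bad], collapse = ", ")))
    }
  }
  tibble::tibble(id = unname(ids), description = unname(desc),
                 sequence = unname(seqs), kind = kind)
}

#' Write sequence records to FASTA
#'
#' @param records Tibble with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @param wrap Line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  header <- ifelse(nzchar(desc),
                   paste0(">", records$id, " ", desc),
                   paste0(">", records$id))
  chunks <- purrr::map2(header, records$sequence, function(h, s) {
    n <- nchar(s)
    if (n == 0) return(h)
    starts <- seq(1L, n, by = wrap)
    c(h, substring(s, starts, pmin(starts + wrap - 1L, n)))
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}

new_gene_models <- function(...) {
  tibble::tibble(...)
}

#' Read gene models from a GFF3 file
#'
#' Parses a strict GFF3 dialect: `gene`, `mRNA`, `exon` and `CDS` features
#' linked by `ID`/`Parent` attributes (other attributes are ignored).
#' Coordinates are stored 1-based inclusive as in the file. Exons and CDS
#' segments are returned in transcription order (descending coordinates for
#' `-` strand genes). For multi-isoform genes the isoform with the longest
#' total CDS is kept and a message is emitted.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `gene_id`, `chromosome`, `strand`, `start`,
#'   `end`, `exons` (list of two-column `start`/`end` matrices in
#'   transcription order), `cds_segments` (same layout) and `cds_complete`
#'   (is the total CDS length divisible by 3?).
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  gff <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")))
  gff$Parent <- vapply(gff$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  genes <- gff[gff$type == "gene", , drop = FALSE]
  mrnas <- gff[gff$type == "mRNA", , drop = FALSE]
  exons <- gff[gff$type == "exon", , drop = FALSE]
  cds <- gff[gff$type == "CDS", , drop = FALSE]

  orphan <- setdiff(stats::na.omit(cds$Parent), c(mrnas$ID, genes$ID))
  if (length(orphan) > 0 || anyNA(cds$Parent)) {
    abort(paste0("CDS feature(s) without a parent gene/mRNA: ",
                 paste(unique(orphan), collapse = ", ")))
  }
  # map every mRNA to its gene; features parented directly on a gene allowed
  mrna_gene <- stats::setNames(mrnas$Parent, mrnas$ID)
  parent_gene <- function(p) ifelse(p %in% names(mrna_gene), mrna_gene[p], p)

  seg_matrix <- function(df, minus_strand, what, gene_id) {
    if (nrow(df) == 0) return(NULL)
    o <- order(df$start)
    if (!identical(o, seq_len(nrow(df)))) {
      # file order is not ascending; accept but say so
      warn(paste0(what, " features of ", gene_id,
                  " out of coordinate order; reordered"))
    }
    df <- df[o, , drop = FALSE]
    if (minus_strand) df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
    cbind(start = df$start, end = df$end)
  }

  models <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gid <- g$ID
    gex <- exons[parent_gene(exons$Parent) == gid, , drop = FALSE]
    gcd <- cds[parent_gene(cds$Parent) == gid, , drop = FALSE]
    gm <- mrnas[mrnas$Parent == gid, , drop = FALSE]
    if (nrow(gm) > 1) {
      # longest-CDS isoform wins
      lens <- vapply(gm$ID, function(m) {
        seg <- gcd[gcd$Parent == m, , drop = FALSE]
        sum(seg$end - seg$start + 1)
      }, numeric(1))
      keep <- gm$ID[which.max(lens)]
      inform(paste0("gene ", gid, ": ", nrow(gm),
                    " isoforms; keeping longest CDS (", keep, ")"))
      gex <- gex[gex$Parent %in% c(keep, gid), , drop = FALSE]
      gcd <- gcd[gcd$Parent %in% c(keep, gid), , drop = FALSE]
    }
    minus <- as.character(g$strand) == "-"
    cds_mat <- seg_matrix(gcd, minus, "CDS", gid)
    cds_len <- if (is.null(cds_mat)) 0 else sum(cds_mat[, "end"] - cds_mat[, "start"] + 1)
    tibble::tibble(
      gene_id = gid,
      chromosome = as.character(g$seqid),
      strand = as.character(g$strand),
      start = as.integer(g$start), end = as.integer(g$end),
      exons = list(seg_matrix(gex, minus, "exon", gid)),
      cds_segments = list(cds_mat),
      cds_complete = cds_len > 0 && cds_len %% 3 == 0)
  })
  dplyr::bind_rows(models)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()]: emits `gene`, `mRNA` (`<gene>.t1`), `exon` and
#' `CDS` rows with `ID`/`Parent` attributes, features in ascending
#' coordinate order.
#'
#' @param models Gene-model tibble as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  rows <- character(0)
  fmt <- function(chrom, type, start, end, strand, attrs) {
    paste(chrom, "p450tools", type, start, end, ".", strand, ".", attrs,
          sep = "\t")
  }
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    gid <- m$gene_id
    tid <- paste0(gid, ".t1")
    rows <- c(rows,
              fmt(m$chromosome, "gene", m$start, m$end, m$strand,
                  paste0("ID=", gid, ";Name=", gid)),
              fmt(m$chromosome, "mRNA", m$start, m$end, m$strand,
                  paste0("ID=", tid, ";Parent=", gid)))
    emit <- function(mat, type) {
      if (is.null(mat)) return(character(0))
      mat <- mat[order(mat[, "start"]), , drop = FALSE]
      vapply(seq_len(nrow(mat)), function(k) {
        fmt(m$chromosome, type, mat[k, "start"], mat[k, "end"], m$strand,
            paste0("ID=", tid, ".", tolower(type), k, ";Parent=", tid))
      }, character(1))
    }
    rows <- c(rows, emit(m$exons[[1]], "exon"), emit(m$cds_segments[[1]], "CDS"))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read an external evidence table
#'
#' Ingests read-only evidence from the two tool dialects commonly used for
#' P450 candidate discovery: `hmmsearch --domtblout` domain hits
#' (`source = "domain_scan"`; the per-domain independent E-value and the
#' alignment coordinates on the target protein are kept) and BLAST/DIAMOND
#' tabular output format 6 (`source = "similarity"`). Comment lines
#' (`#`) are skipped; malformed rows are skipped with a message giving the
#' line number.
#'
#' @param path Path to the table.
#' @param dialect `"hmmsearch_domtblout"` or `"blast_outfmt6"`.
#' @return Tibble with columns `query_id`, `source`, `score`, `evalue`,
#'   `region_start`, `region_end`.
#' @export
read_evidence_table <- function(path,
                                dialect = c("hmmsearch_domtblout",
                                            "blast_outfmt6")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  k <- 0L
  for (ln in which(keep)) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    row <- NULL
    if (dialect == "hmmsearch_domtblout" && length(f) >= 21) {
      ev <- suppressWarnings(as.numeric(f[13]))
      sc <- suppressWarnings(as.numeric(f[14]))
      rs <- suppressWarnings(as.integer(f[18]))
      re <- suppressWarnings(as.integer(f[19]))
      if (!anyNA(c(ev, sc, rs, re)) && ev >= 0) {
        row <- tibble::tibble(query_id = f[1], source = "domain_scan",
                              score = sc, evalue = ev,
                              region_start = rs, region_end = re)
      }
    } else if (dialect == "blast_outfmt6" && length(f) >= 12) {
      ev <- suppressWarnings(as.numeric(f[11]))
      sc <- suppressWarnings(as.numeric(f[12]))
      rs <- suppressWarnings(as.integer(f[7]))
      re <- suppressWarnings(as.integer(f[8]))
      if (!anyNA(c(ev, sc, rs, re)) && ev >= 0) {
        row <- tibble::tibble(query_id = f[1], source = "similarity",
                              score = sc, evalue = ev,
                              region_start = rs, region_end = re)
      }
    }
    if (is.null(row)) {
      inform(paste0("skipping malformed evidence row at line ", ln))
    } else {
      k <- k + 1L
      out[[k]] <- row
    }
  }
  if (k == 0L) {
    return(tibble::tibble(query_id = character(), source = character(),
                          score = numeric(), evalue = numeric(),
                          region_start = integer(), region_end = integer()))
  }
  dplyr::bind_rows(out[seq_len(k)])
}
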