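VALID_PARTIAL_FLAGS <- c("00", "01", "10", "11")

# Internal constructor/validator for the MAG-labeled ORF catalog.
# `kos` is a list-column of character vectors (possibly empty).
new_gene_table <- function(gene_id, mag_id, length_nt, partial, kos) {
  tbl <- tibble(
    gene_id = as.character(gene_id),
    mag_id = as.character(mag_id),
    length_nt = as.integer(length_nt),
    partial = as.character(partial),
    kos = kos
  )
  validate_gene_table(tbl)
  class(tbl) <- c("mf_gene_table", class(tbl))
  tbl
}

validate_gene_table <- function(tbl, context = "gene table") {
  dup <- tbl$gene_id[duplicated(tbl$gene_id)]
  if (length(dup) > 0L) {
    stop(sprintf("%s: duplicate gene_id '%s'", context, dup[1]), call. = FALSE)
  }
  bad_len <- which(is.na(tbl$length_nt) | tbl$length_nt < 3L)
  if (length(bad_len) > 0L) {
    stop(sprintf("%s: non-positive or missing length for gene '%s' (row %d)",
                 context, tbl$gene_id[bad_len[1]], bad_len[1]), call. = FALSE)
  }
  bad_flag <- which(!tbl$partial %in% VALID_PARTIAL_FLAGS)
  if (length(bad_flag) > 0L) {
    stop(sprintf("%s: invalid partial flag '%s' for gene '%s' (row %d)",
                 context, tbl$partial[bad_flag[1]], tbl$gene_id[bad_flag[1]],
                 bad_flag[1]), call. = FALSE)
  }
  if (any(is.na(tbl$mag_id) | !nzchar(tbl$mag_id))) {
    stop(sprintf("%s: empty mag_id", context), call. = FALSE)
  }
  invisible(tbl)
}

#' Read a MAG-labeled gene table
#'
#' Ingests the merged ORF catalog as a TSV with header columns `gene_id`,
#' `mag_id`, `length_nt`, `partial` (Prodigal two-character completeness flag,
#' `"00"` = both gene ends intact), and `ko` (blank, a single KO, or a
#' semicolon-separated list).
#'
#' @param path Path to the gene TSV.
#' @return A `mf_gene_table` tibble with a `kos` list-column.
#' @export
read_gene_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      mag_id = readr::col_character(),
      length_nt = readr::col_integer(),
      partial = readr::col_character(),
      ko = readr::col_character()
    )
  )
  required <- c("gene_id", "mag_id", "length_nt", "partial", "ko")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0L) {
    stop(sprintf("gene TSV '%s' lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  kos <- lapply(tbl$ko, parse_ko_field)
  new_gene_table(tbl$gene_id, tbl$mag_id, tbl$length_nt, tbl$partial, kos)
}

parse_ko_field <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  kos <- toupper(trimws(strsplit(x, ";", fixed = TRUE)[[1]]))
  kos <- kos[nzchar(kos)]
  bad <- kos[!grepl(KO_PATTERN, kos)]
  if (length(bad) > 0L) {
    stop(sprintf("malformed KO '%s' in annotation field '%s'", bad[1], x),
         call. = FALSE)
  }
  unique(kos)
}

#' Read Prodigal gene predictions from GFF
#'
#' Parses CDS features from a Prodigal GFF3 file for one MAG. Gene length is
#' `end - start + 1` (1-based inclusive coordinates); the completeness flag is
#' taken verbatim from the `partial=XY` attribute, defaulting to `"00"` with a
#' warning when absent.
#'
#' @param path Path to the GFF file.
#' @param mag_id MAG label applied to every record.
#' @return A `mf_gene_table` tibble (no KO assignments yet).
#' @export
read_prodigal_gff <- function(path, mag_id) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    stop(sprintf("no features in GFF '%s'", path), call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  cds <- Filter(function(f) length(f) >= 9L && f[3] == "CDS", fields)
  recs <- lapply(seq_along(cds), function(i) {
    f <- cds[[i]]
    attrs <- f[9]
    id_match <- regmatches(attrs, regexpr("ID=[^;]+", attrs))
    gene_id <- if (length(id_match) == 1L) {
      sub("^ID=", "", id_match)
    } else {
      sprintf("%s_gene%d", mag_id, i)
    }
    partial_match <- regmatches(attrs, regexpr("partial=[01]{2}", attrs))
    partial <- if (length(partial_match) == 1L) {
      sub("^partial=", "", partial_match)
    } else {
      warning(sprintf("GFF feature '%s' lacks a partial attribute; assuming 00",
                      gene_id), call. = FALSE)
      "00"
    }
    list(gene_id = paste(mag_id, gene_id, sep = "|"),
         length_nt = as.integer(f[5]) - as.integer(f[4]) + 1L,
         partial = partial)
  })
  new_gene_table(
    gene_id = vapply(recs, `[[`, character(1), "gene_id"),
    mag_id = rep(mag_id, length(recs)),
    length_nt = vapply(recs, `[[`, integer(1), "length_nt"),
    partial = vapply(recs, `[[`, character(1), "partial"),
    kos = rep(list(character(0)), length(recs))
  )
}

#' Merge per-MAG gene tables into one ORF catalog
#'
#' @param ... `mf_gene_table` objects (or a single list of them).
#' @return The merged `mf_gene_table`; errors on gene_id collisions.
#' @export
merge_gene_tables <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "mf_gene_table")) {
    parts <- parts[[1]]
  }
  merged <- dplyr::bind_rows(lapply(parts, function(p) {
    class(p) <- setdiff(class(p), "mf_gene_table")
    p
  }))
  validate_gene_table(merged, context = "merged gene table")
  class(merged) <- c("mf_gene_table", class(merged))
  merged
}

#' Attach KO annotations to a gene table
#'
#' Merges a GhostKOALA-style two-column TSV (`gene_id<TAB>KO`, KO possibly
#' blank, no header by default) onto the catalog. Genes absent from the TSV
#' keep their existing KO list; rows naming unknown genes are collected into
#' an orphan report rather than failing.
#'
#' @param table A `mf_gene_table`.
#' @param path Path to the annotation TSV.
#' @param header Does the TSV carry a header row? GhostKOALA output does not.
#' @return The annotated table, with the orphan rows (unknown gene ids) in
#'   attribute `"orphans"`.
#' @export
attach_ko_annotations <- function(table, path, header = FALSE) {
  ann <- readr::read_tsv(
    path,
    col_names = if (header) TRUE else c("gene_id", "ko"),
    skip = if (header) 0L else 0L,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (header) names(ann)[1:2] <- c("gene_id", "ko")
  ann <- ann[!is.na(ann$gene_id), , drop = FALSE]
  known <- match(ann$gene_id, table$gene_id)
  orphans <- ann[is.na(known), , drop = FALSE]
  hits <- ann[!is.na(known), , drop = FALSE]
  hit_idx <- known[!is.na(known)]
  kos <- table$kos
  for (i in seq_len(nrow(hits))) {
    new_kos <- parse_ko_field(hits$ko[i])
    kos[[hit_idx[i]]] <- unique(c(kos[[hit_idx[i]]], new_kos))
  }
  table$kos <- kos
  attr(table, "orphans") <- tibble(gene_id = orphans$gene_id,
                                   ko = orphans$ko)
  table
}

#' Proportion of full-length genes
#'
#' QC metric: the fraction of ORFs whose Prodigal partial flag is `"00"`
#' (complete at both ends). Partial ORFs stay in all downstream expression
#' computations; this fraction only characterizes assembly quality.
#'
#' @param table A `mf_gene_table`.
#' @return A fraction in `[0, 1]`.
#' @export
full_length_fraction <- function(table) {
  if (nrow(table) == 0L) {
    stop("full_length_fraction: empty gene table", call. = FALSE)
  }
  mean(table$partial == "00")
}

#' Write a gene table to TSV
#'
#' Inverse of [read_gene_table()]: KO lists are serialized semicolon-joined.
#'
#' @param table A `mf_gene_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(table, path) {
  out <- tibble(
    gene_id = table$gene_id,
    mag_id = table$mag_id,
    length_nt = table$length_nt,
    partial = table$partial,
    ko = vapply(table$kos, paste, character(1), collapse = ";")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

# mag -> set of KOs encoded anywhere in its genes
mag_ko_sets <- function(table) {
  split_kos <- split(table$kos, table$mag_id)
  lapply(split_kos, function(lst) unique(unlist(lst, use.names = FALSE)))
}
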