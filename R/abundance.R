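#' Construct a taxa-by-samples abundance table
#'
#' @param counts non-negative numeric matrix, taxa x samples. Integer
#'   counts by default; set `integer_counts = FALSE` for tables holding
#'   relative abundances.
#' @param taxonomy character vector of taxon labels, either full
#'   Greengenes-style lineage strings (`"k__...; p__...; ...; g__..."`)
#'   or bare genus labels; defaults to rownames of `counts`.
#' @param metadata optional data.frame with a `sample` column covering
#'   every sample, plus e.g. `time` (days) or `group`.
#' @param integer_counts require whole-number counts.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(counts, taxonomy = rownames(counts),
                            metadata = NULL, integer_counts = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(taxonomy)) taxonomy <- paste0("T", seq_len(nrow(counts)))
  if (length(taxonomy) != nrow(counts)) {
    stop("`taxonomy` must have one entry per row of `counts`")
  }
  if (anyDuplicated(taxonomy)) {
    stop("duplicate taxon labels: ",
         paste(unique(taxonomy[duplicated(taxonomy)]), collapse = ", "))
  }
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (integer_counts && any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be whole numbers")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  }
  if (anyDuplicated(colnames(counts))) stop("duplicate sample labels")
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"sample" %in% names(metadata)) {
      stop("`metadata` must contain a `sample` column")
    }
    missing <- setdiff(colnames(counts), metadata$sample)
    if (length(missing)) {
      stop("metadata missing for sample(s): ",
           paste(missing, collapse = ", "))
    }
    metadata <- metadata[match(colnames(counts), metadata$sample), ,
                         drop = FALSE]
    rownames(metadata) <- NULL
  }
  rownames(counts) <- taxonomy
  structure(list(counts = counts, taxonomy = taxonomy,
                 metadata = metadata),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table:", nrow(x$counts), "taxa x", ncol(x$counts),
      "samples\n")
  if (!is.null(x$metadata)) {
    cat("  metadata fields:",
        paste(setdiff(names(x$metadata), "sample"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Write an abundance table as TSV
#'
#' First column `taxonomy`, remaining columns samples; `#`-prefixed header
#' lines carry sample metadata (`#meta <field> <values...>`) so that
#' [read_table()] round-trips the object.
#'
#' @param table an [abundance_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(table$metadata)) {
    for (field in setdiff(names(table$metadata), "sample")) {
      writeLines(paste(c("#meta", field,
                         as.character(table$metadata[[field]])),
                       collapse = "\t"), con)
    }
  }
  writeLines(paste(c("taxonomy", colnames(table$counts)), collapse = "\t"),
             con)
  body <- apply(table$counts, 1, paste, collapse = "\t")
  writeLines(paste(table$taxonomy, body, sep = "\t"), con)
  invisible(path)
}

#' Read an abundance table (TSV or BIOM-JSON)
#'
#' The TSV dialect has a first column `taxonomy` (semicolon-separated
#' lineage, Greengenes rank prefixes) and one column per sample; comment
#' lines start with `#`, and `#meta` lines are parsed back into sample
#' metadata. BIOM reading (JSON flavor) requires the `biomformat`
#' package.
#'
#' @param path input file.
#' @param format `"tsv"` or `"biom-json"`.
#' @return An [abundance_table]. Malformed rows are reported with their
#'   line numbers.
#' @export
read_table <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom-json") return(read_biom_table(path))
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- startsWith(lines, "#")
  meta_lines <- lines[startsWith(lines, "#meta\t")]
  body_idx <- which(!is_comment & nzchar(lines))
  if (!length(body_idx)) stop("no table content found in ", path)
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  if (header[1] != "taxonomy") {
    stop("line ", body_idx[1], ": first column must be 'taxonomy'")
  }
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample labels: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  rows_idx <- body_idx[-1]
  fields <- strsplit(lines[rows_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(header))
  if (length(bad)) {
    stop("ragged row(s) at line(s) ",
         paste(rows_idx[bad], collapse = ", "),
         ": expected ", length(header), " fields")
  }
  taxonomy <- vapply(fields, `[[`, character(1), 1)
  counts <- matrix(NA_real_, length(fields), length(samples),
                   dimnames = list(taxonomy, samples))
  for (r in seq_along(fields)) {
    vals <- suppressWarnings(as.numeric(fields[[r]][-1]))
    if (anyNA(vals)) {
      stop("line ", rows_idx[r], " (", taxonomy[r],
           "): non-numeric count in column '",
           samples[which(is.na(vals))[1]], "'")
    }
    neg <- which(vals < 0)
    if (length(neg)) {
      stop("line ", rows_idx[r], " (", taxonomy[r],
           "): negative count in column '", samples[neg[1]], "'")
    }
    nonint <- which(abs(vals - round(vals)) > 1e-8)
    if (length(nonint)) {
      stop("line ", rows_idx[r], " (", taxonomy[r],
           "): non-integer count in column '", samples[nonint[1]], "'")
    }
    counts[r, ] <- vals
  }
  metadata <- NULL
  if (length(meta_lines)) {
    metadata <- data.frame(sample = samples, stringsAsFactors = FALSE)
    for (ml in meta_lines) {
      parts <- strsplit(ml, "\t", fixed = TRUE)[[1]]
      if (length(parts) != length(samples) + 2) {
        stop("malformed #meta line (expected ", length(samples),
             " values): ", ml)
      }
      vals <- parts[-(1:2)]
      num <- suppressWarnings(as.numeric(vals))
      metadata[[parts[2]]] <- if (anyNA(num)) vals else num
    }
  }
  abundance_table(counts, taxonomy = taxonomy, metadata = metadata)
}

read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("reading BIOM files requires the 'biomformat' package")
  }
  b <- biomformat::read_biom(path)
  counts <- as(biomformat::biom_data(b), "matrix")
  om <- biomformat::observation_metadata(b)
  taxonomy <- rownames(counts)
  if (!is.null(om) && length(om)) {
    lineages <- if (is.data.frame(om)) {
      apply(om, 1, function(r) paste(r[nzchar(r)], collapse = "; "))
    } else {
      vapply(om, function(r) paste(unlist(r), collapse = "; "),
             character(1))
    }
    if (all(nzchar(lineages))) taxonomy <- unname(lineages)
  }
  abundance_table(counts, taxonomy = taxonomy)
}

# Parse a Greengenes-style lineage into named ranks. A bare label with no
# rank prefixes is treated as an already-collapsed genus label.
parse_lineage <- function(lineage) {
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  has_prefix <- grepl("^[kpcofgs]__", parts)
  if (!any(has_prefix)) {
    if (!nzchar(trimws(lineage))) stop("empty taxon label")
    return(c(g = trimws(lineage)))
  }
  parts <- parts[has_prefix]
  ranks <- substr(parts, 1, 1)
  vals <- sub("^[kpcofgs]__", "", parts)
  stats::setNames(vals, ranks)
}

genus_label <- function(lineage) {
  ranks <- parse_lineage(lineage)
  g <- if ("g" %in% names(ranks)) ranks[["g"]] else ""
  if (nzchar(g)) return(g)
  named <- ranks[names(ranks) != "s" & nzchar(ranks)]
  if (!length(named)) {
    stop("lineage with no parsable named ranks: '", lineage, "'")
  }
  paste0("unclassified_", named[[length(named)]])
}

#' Collapse an abundance table to the genus level
#'
#' Rows sharing a genus are summed. Rows whose lineage has an empty genus
#' field are labeled `unclassified_<lowest named rank>` (typically the
#' family). Idempotent: applying it to an already-collapsed table is a
#' no-op.
#'
#' @param table an [abundance_table] with lineage-string taxonomy.
#' @return A genus-level [abundance_table]; column sums are conserved.
#' @export
collapse_to_genus <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  genera <- vapply(table$taxonomy, genus_label, character(1),
                   USE.NAMES = FALSE)
  counts <- rowsum(table$counts, group = genera, reorder = FALSE)
  abundance_table(counts, taxonomy = rownames(counts),
                  metadata = table$metadata,
                  integer_counts = FALSE)
}

#' Convert counts to per-sample relative abundances
#'
#' @param table an [abundance_table].
#' @return An [abundance_table] whose columns sum to 1.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  totals <- colSums(table$counts)
  zero <- which(totals == 0)
  if (length(zero)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(table$counts)[zero], collapse = ", "))
  }
  abundance_table(sweep(table$counts, 2, totals, "/"),
                  taxonomy = table$taxonomy, metadata = table$metadata,
                  integer_counts = FALSE)
}

#' Build a time-series profile from a table with time metadata
#'
#' Samples (animals) sharing a time point are aggregated by the
#' arithmetic mean of their relative abundances; time points are ordered
#' increasingly.
#'
#' @param table an [abundance_table] whose metadata contains a numeric
#'   `time` column.
#' @return A normalized [ts_profile].
#' @export
to_profile <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$metadata) || !"time" %in% names(table$metadata)) {
    stop("`table` must carry numeric `time` metadata for every sample")
  }
  rel <- to_relative(table)
  times <- sort(unique(as.numeric(table$metadata$time)))
  ab <- vapply(times, function(tt) {
    cols <- which(as.numeric(table$metadata$time) == tt)
    rowMeans(rel$counts[, cols, drop = FALSE])
  }, numeric(nrow(rel$counts)))
  ts_profile(ab, times, taxa = rel$taxonomy)
}
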