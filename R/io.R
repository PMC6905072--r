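#' Read an expression matrix with its sample metadata
#'
#' The expression file is tab-delimited with gene identifiers in the first
#' column and one column per sample; the metadata file is tab-delimited with
#' one row per sample and at least the columns `sample_id`, `genotype`,
#' `treatment`, `t_dev`, `t_heat`, `t_rec`, `split`. Samples are returned in
#' the column order of the expression file; metadata are joined by
#' `sample_id` and any metadata rows without a matching column are dropped
#' with a warning.
#'
#' @param path Path to the tab-delimited expression matrix.
#' @param meta_path Path to the tab-delimited sample metadata.
#' @param allow_na How to treat missing expression values: `"error"`
#'   (default) or `"drop_gene"` to drop genes containing any NA, with a
#'   warning.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, meta_path, allow_na = c("error", "drop_gene")) {
  allow_na <- match.arg(allow_na)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L)
    stop("expression file must have a gene-id column plus >= 1 sample column")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicated gene identifier(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)])[1:5], collapse = ", "))
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicated sample identifier(s) in header of ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  values <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                   dimnames = list(ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & trimws(col) != "" &
                   toupper(trimws(col)) != "NA")
    if (length(bad) > 0L)
      stop("non-numeric value '", col[bad[1L]], "' at gene '", ids[bad[1L]],
           "', sample '", sample_ids[j], "'")
    num[!is.na(col) & (trimws(col) == "" | toupper(trimws(col)) == "NA")] <- NA_real_
    values[, j] <- num
  }
  if (anyNA(values)) {
    if (allow_na == "error") {
      bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
      stop("missing value at gene '", ids[bad[1L]], "', sample '",
           sample_ids[bad[2L]], "' (set allow_na = 'drop_gene' to drop)")
    }
    drop <- apply(values, 1L, anyNA)
    warning("dropping ", sum(drop), " gene(s) with missing values")
    values <- values[!drop, , drop = FALSE]
    if (nrow(values) == 0L) stop("all genes dropped due to missing values")
  }
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta))
    stop("metadata file must contain a 'sample_id' column")
  missing_meta <- setdiff(sample_ids, meta$sample_id)
  if (length(missing_meta) > 0L)
    stop("sample(s) present in expression matrix but absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  extra <- setdiff(meta$sample_id, sample_ids)
  if (length(extra) > 0L)
    warning("metadata row(s) without expression column dropped: ",
            paste(extra, collapse = ", "))
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  expression_dataset(values, meta)
}

#' Write an expression dataset to disk
#'
#' Writes the tab-delimited matrix (gene IDs in a leading `gene_id` column)
#' and the sample metadata, the inverse of [read_expression()].
#'
#' @param ds An `expr_dataset`.
#' @param path Output path for the expression matrix.
#' @param meta_path Output path for the sample metadata.
#' @return Invisibly, `ds`.
#' @export
write_expression <- function(ds, path, meta_path) {
  out <- data.frame(gene_id = gene_ids(ds), ds$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ds)
}

#' Survival table constructor
#'
#' One row per observed death (or censoring event): `genotype`, `treatment`
#' (`"control"` or `"heat"`), `day` (integer day of death, 1-based days post
#' age-synchronization) and `status` (1 = event, 0 = censored).
#'
#' @param genotype,treatment,day Vectors of equal length.
#' @param status Event indicator, default all 1 (observed death).
#' @return A data frame of class `survival_table`.
#' @export
survival_table <- function(genotype, treatment, day, status = 1L) {
  df <- data.frame(genotype = as.character(genotype),
                   treatment = as.character(treatment),
                   day = as.numeric(day),
                   status = as.integer(status),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$treatment), c("control", "heat"))
  if (length(bad) > 0L)
    stop("invalid survival treatment value(s): ", paste(bad, collapse = ", "))
  if (any(df$day < 1)) stop("days of death must be >= 1")
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Read lifespan data in cumulative-death format
#'
#' Parses a tab-delimited table with columns `genotype`, `treatment` and
#' day columns `X1`, `X2`, ... giving the cumulative number of dead animals
#' on each day. Per-day death counts are recovered by first differences and
#' expanded into one event per animal.
#'
#' @param path Path to the tab-delimited cumulative table.
#' @return A [survival_table()]. Rows of the input whose final cumulative
#'   count is zero contribute no events and are reported with a warning.
#' @examples
#' tf <- tempfile()
#' writeLines(c("genotype\ttreatment\tX1\tX2\tX3\tX4",
#'              "RIL01\tcontrol\t0\t2\t5\t5"), tf)
#' read_survival_cumulative(tf)$day  # 2 2 3 3 3
#' @export
read_survival_cumulative <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("genotype", "treatment") %in% names(raw)))
    stop("cumulative survival file must have 'genotype' and 'treatment' columns")
  day_cols <- grep("^X?[0-9]+$", names(raw), value = TRUE)
  if (length(day_cols) == 0L)
    stop("no day columns (X1, X2, ...) found in ", path)
  days <- as.integer(sub("^X", "", day_cols))
  ord <- order(days)
  day_cols <- day_cols[ord]
  days <- days[ord]
  rows <- vector("list", nrow(raw))
  empty <- character(0)
  for (i in seq_len(nrow(raw))) {
    cum <- as.numeric(unlist(raw[i, day_cols]))
    cum[is.na(cum)] <- if (all(is.na(cum))) 0 else NA
    if (anyNA(cum)) {
      # carry last observation forward over trailing NAs only
      for (j in seq_along(cum)) if (is.na(cum[j])) cum[j] <- if (j == 1L) 0 else cum[j - 1L]
    }
    dec <- which(diff(cum) < 0)
    if (length(dec) > 0L)
      stop("cumulative death count decreases for genotype '", raw$genotype[i],
           "' (", raw$treatment[i], ") at day ", days[dec[1L] + 1L])
    deaths <- diff(c(0, cum))
    if (sum(deaths) == 0) {
      empty <- c(empty, paste0(raw$genotype[i], "/", raw$treatment[i]))
      next
    }
    rows[[i]] <- data.frame(genotype = raw$genotype[i],
                            treatment = raw$treatment[i],
                            day = rep(days, deaths),
                            status = 1L, stringsAsFactors = FALSE)
  }
  if (length(empty) > 0L)
    warning("row(s) with zero recorded deaths are unusable: ",
            paste(empty, collapse = ", "))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no deaths recorded in ", path)
  df <- do.call(rbind, rows)
  survival_table(df$genotype, df$treatment, df$day, df$status)
}

#' Write a survival table in cumulative-death format
#'
#' @param surv A [survival_table()].
#' @param path Output path.
#' @param n_days Number of day columns to write; defaults to the latest
#'   observed day.
#' @return Invisibly, `surv`.
#' @export
write_survival_cumulative <- function(surv, path, n_days = NULL) {
  if (is.null(n_days)) n_days <- max(surv$day)
  key <- unique(surv[, c("genotype", "treatment")])
  mat <- matrix(0, nrow = nrow(key), ncol = n_days)
  for (i in seq_len(nrow(key))) {
    d <- surv$day[surv$genotype == key$genotype[i] &
                    surv$treatment == key$treatment[i]]
    counts <- tabulate(d, nbins = n_days)
    mat[i, ] <- cumsum(counts)
  }
  out <- data.frame(key, mat, check.names = FALSE)
  names(out) <- c("genotype", "treatment", paste0("X", seq_len(n_days)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(surv)
}

#' Read gene sets in GMT format
#'
#' Each line is `set_name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicated members within a set are counted once (with a warning), and
#' lines without members are skipped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of class
#'   `gene_set_collection`, with set descriptions in the
#'   `"descriptions"` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (length(parts) < 3L || length(members) == 0L) {
      warning("skipping empty gene set line: '", parts[1L], "'")
      next
    }
    if (anyDuplicated(members)) {
      warning("duplicated member(s) in set '", parts[1L], "' counted once")
      members <- unique(members)
    }
    sets[[parts[1L]]] <- members
    desc[parts[1L]] <- parts[2L]
  }
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' Write gene sets in GMT format
#'
#' @param sets A `gene_set_collection` (or named list of character vectors).
#' @param path Output path.
#' @return Invisibly, `sets`.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}
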