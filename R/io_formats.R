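#' Convert a two-sided p-value and a sign into a signed z-score
#'
#' The magnitude is the upper-tail two-sided quantile,
#' `z = qnorm(1 - p/2) * sign`, the standard convention for recovering a
#' z-score from a DE p-value paired with the sign of the log fold change.
#' p-values are clamped below at `eps` before the transform so that extremely
#' small inputs do not map to infinity.
#'
#' @param p numeric vector of two-sided p-values in (0, 1].
#' @param sign numeric vector of signs (+1/-1), recycled.
#' @param eps lower clamp applied to `p` (default 1e-300).
#' @return Numeric vector of signed z-scores.
#' @export
zscore_from_pvalue <- function(p, sign = 1, eps = 1e-300) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p <- pmax(p, eps)
  # upper-tail form stays accurate for very small p
  qnorm(p / 2, lower.tail = FALSE) * base::sign(sign)
}

#' Back-derive a standard error from an effect size and z-score
#'
#' `se = |beta_hat / z|`. Genes with `z == 0` have no defined standard error
#' and are returned as `NA` so callers can flag and exclude them.
#'
#' @param beta_hat numeric vector of effect size estimates.
#' @param z numeric vector of signed z-scores.
#' @return Numeric vector of standard errors; `NA` where `z == 0`.
#' @export
se_from_beta_and_z <- function(beta_hat, z) {
  out <- abs(beta_hat / z)
  out[z == 0] <- NA_real_
  out
}

.complete_gene_stats <- function(df) {
  has <- function(v) v %in% names(df) && !all(is.na(df[[v]]))
  if (has("beta_hat") && has("se")) {
    df$z <- df$beta_hat / df$se
    df$p <- 2 * pnorm(-abs(df$z))
  } else if (has("beta_hat") && has("p")) {
    df$z <- zscore_from_pvalue(df$p, sign(df$beta_hat))
    df$se <- se_from_beta_and_z(df$beta_hat, df$z)
  } else if (has("z")) {
    df$p <- 2 * pnorm(-abs(df$z))
    if (!has("beta_hat")) df$beta_hat <- df$z
    if (!has("se")) df$se <- rep(1, nrow(df))
  } else if (has("p") && has("sign")) {
    df$z <- zscore_from_pvalue(df$p, df$sign)
    df$beta_hat <- df$z
    df$se <- rep(1, nrow(df))
  } else {
    stop("cannot complete summary statistics: need (beta_hat, se), ",
         "(beta_hat, p), z, or (p, sign)")
  }
  df[c("gene_id", "beta_hat", "se", "z", "p")]
}

#' Read a table of per-gene DE summary statistics
#'
#' Reads a delimited text file with a header and returns a validated table
#' with columns `gene_id`, `beta_hat`, `se`, `z`, `p`, completing missing
#' fields from the available ones (`z = beta_hat/se`,
#' `p = 2 * (1 - pnorm(|z|))`, `se = |beta_hat/z|`). Rows with non-finite
#' values or non-positive standard errors are dropped with a reported count;
#' duplicated gene identifiers are an error.
#'
#' @param path path to a TSV (default) or CSV file with a header.
#' @param columns named list mapping the canonical names `gene`, `beta_hat`,
#'   `se`, `z`, `p`, `sign` to column names in the file. Unmapped canonical
#'   names are looked up verbatim.
#' @param sep field separator; guessed from the file extension when `NULL`.
#' @param max_p optional cutoff: genes with completed p-value above it are
#'   removed (with a reported count). Useful when an upstream DE tool's null
#'   p-values pile up near 1, which distorts the mixture fit; off by
#'   default since its applicability is data-set specific.
#' @return A `data.frame` with columns `gene_id`, `beta_hat`, `se`, `z`, `p`
#'   and attribute `n_dropped` (number of invalid rows removed).
#' @export
read_summary_stats <- function(path, columns = list(), sep = NULL,
                               max_p = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (nrow(raw) == 0) stop("empty summary-statistics file: ", path)
  pick <- function(canon, default = canon) {
    nm <- if (!is.null(columns[[canon]])) columns[[canon]] else default
    if (nm %in% names(raw)) raw[[nm]] else NULL
  }
  gene <- pick("gene", "gene_id")
  if (is.null(gene)) gene <- raw[[1]]
  gene <- as.character(gene)
  dup <- gene[duplicated(gene)]
  if (length(dup)) stop("duplicated gene_id in summary statistics: ",
                        paste(unique(dup), collapse = ", "))
  df <- data.frame(gene_id = gene, stringsAsFactors = FALSE)
  for (v in c("beta_hat", "se", "z", "p", "sign")) {
    col <- pick(v)
    if (!is.null(col)) df[[v]] <- as.numeric(col)
  }
  df <- .complete_gene_stats(df)
  bad <- !is.finite(df$beta_hat) | !is.finite(df$se) | df$se <= 0 |
    !is.finite(df$z) | !is.finite(df$p)
  n_dropped <- sum(bad)
  if (n_dropped) {
    message(n_dropped, " gene(s) dropped: non-finite fields or se <= 0")
    df <- df[!bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  if (!is.null(max_p)) {
    n_filtered <- sum(df$p > max_p)
    if (n_filtered) {
      message(n_filtered, " gene(s) removed with p > ", max_p)
      df <- df[df$p <= max_p, , drop = FALSE]
      rownames(df) <- NULL
    }
    n_dropped <- n_dropped + n_filtered
  }
  attr(df, "n_dropped") <- n_dropped
  df
}

#' Build a summary-statistics table from vectors
#'
#' In-memory counterpart of [read_summary_stats()]: completes and validates
#' the (`beta_hat`, `se`, `z`, `p`) fields from whichever are supplied.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param beta_hat,se,z,p,sign optional numeric vectors.
#' @return A validated `data.frame` as from [read_summary_stats()].
#' @export
gene_stats <- function(gene_id, beta_hat = NULL, se = NULL, z = NULL,
                       p = NULL, sign = NULL) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("duplicated gene_id")
  df <- data.frame(gene_id = gene_id, stringsAsFactors = FALSE)
  if (!is.null(beta_hat)) df$beta_hat <- beta_hat
  if (!is.null(se)) df$se <- se
  if (!is.null(z)) df$z <- z
  if (!is.null(p)) df$p <- p
  if (!is.null(sign)) df$sign <- sign
  .complete_gene_stats(df)
}

#' Write a summary-statistics table
#'
#' Emits the canonical columns `gene_id`, `beta_hat`, `se`, `z`, `p` as TSV
#' with enough digits for a lossless round trip at 10 significant digits.
#'
#' @param stats table from [read_summary_stats()] or [gene_stats()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  out <- stats[c("gene_id", "beta_hat", "se", "z", "p")]
  for (v in c("beta_hat", "se", "z", "p"))
    out[[v]] <- formatC(out[[v]], digits = 15, format = "g")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene set collection over a gene universe
#'
#' @param universe character vector of gene identifiers (typically the genes
#'   present in the summary-statistics table).
#' @param sets named list of character vectors of member genes; members
#'   outside the universe are ignored.
#' @param provenance optional character vector of category labels per set.
#' @return An object of class `gene_set_collection` storing, per set, the
#'   indices of member genes in the universe.
#' @export
gene_set_collection <- function(universe, sets, provenance = NULL) {
  universe <- as.character(universe)
  stopifnot(!anyDuplicated(universe), is.list(sets), !is.null(names(sets)))
  idx <- lapply(sets, function(g) sort(unique(match(g, universe))))
  idx <- lapply(idx, function(i) i[!is.na(i)])
  structure(list(universe = universe, sets = idx, provenance = provenance),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "set(s) over",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Sizes and coverage rates of a gene set collection
#'
#' @param collection a `gene_set_collection`.
#' @return Named integer vector of set sizes (`set_sizes`) or named numeric
#'   vector of coverage rates, size / universe size (`coverage_rates`).
#' @export
set_sizes <- function(collection) {
  vapply(collection$sets, length, integer(1))
}

#' @rdname set_sizes
#' @export
coverage_rates <- function(collection) {
  set_sizes(collection) / length(collection$universe)
}

#' Binary membership vector of one gene set
#'
#' @param collection a `gene_set_collection`.
#' @param set_name name of the set.
#' @return Integer 0/1 vector over the universe.
#' @export
set_membership <- function(collection, set_name) {
  idx <- collection$sets[[set_name]]
  if (is.null(idx)) stop("unknown gene set: ", set_name)
  a <- integer(length(collection$universe))
  a[idx] <- 1L
  a
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines `set_name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Member genes absent from the universe are silently ignored (their count is
#' reported via a message); duplicate set names are disambiguated by suffixing
#' `_2`, `_3`, ...
#'
#' @param path path to a GMT file.
#' @param universe character vector of gene identifiers to intersect with.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, universe) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short))
    stop("malformed GMT line (fewer than 3 fields) at line ", short[1])
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(members) <- .disambiguate(vapply(fields, `[[`, character(1), 1L))
  n_outside <- sum(vapply(members, function(g) sum(!g %in% universe), numeric(1)))
  if (n_outside)
    message(n_outside, " gene-set member(s) outside the universe ignored")
  gene_set_collection(universe, members)
}

.disambiguate <- function(nm) {
  out <- nm
  tab <- table(nm)
  for (d in names(tab[tab > 1])) {
    at <- which(nm == d)
    out[at[-1]] <- paste0(d, "_", seq_along(at[-1]) + 1L)
  }
  out
}

#' Read gene sets in two-column long format
#'
#' A TSV with a header and columns `set` and `gene` (one membership per row),
#' a convenient dialect for gene annotation exports.
#'
#' @inheritParams read_gmt
#' @return A `gene_set_collection`.
#' @export
read_gene_sets_long <- function(path, universe) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("set", "gene") %in% names(df)))
    stop("long-format gene set file needs columns 'set' and 'gene'")
  sets <- split(as.character(df$gene), as.character(df$set))
  gene_set_collection(universe, sets)
}

#' Prune small gene sets
#'
#' Removes sets whose size, measured after intersection with the universe,
#' is below `min_size`. The conventional default of 20 follows the common
#' practice of excluding gene sets with fewer than 20 genes, for which
#' enrichment parameter estimates are unstable.
#'
#' @param collection a `gene_set_collection`.
#' @param min_size minimum retained set size (>= 1).
#' @return A pruned `gene_set_collection`; the number of sets removed is in
#'   attribute `n_removed`.
#' @export
prune_gene_sets <- function(collection, min_size = 20) {
  stopifnot(min_size >= 1)
  keep <- set_sizes(collection) >= min_size
  out <- collection
  out$sets <- collection$sets[keep]
  if (!is.null(collection$provenance))
    out$provenance <- collection$provenance[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}
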