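#' Read a multi-omics network from weighted edge lists
#'
#' Accepts either three files (gene-gene, metabolite-metabolite,
#' gene-metabolite) of tab- or space-separated `node_a node_b weight` rows,
#' or one file with a fourth `block` column tagging each row `gg`, `mm` or
#' `gm`. The format matches the STRING/STITCH convention of confidence
#' scores between 0 and 999; weights outside that range are rejected for
#' `weight_scale = "raw_confidence"`.
#'
#' Node types are inferred from where an identifier appears (both columns
#' of gg rows are genes, both columns of mm rows are metabolites, gm rows
#' are gene then metabolite); an identifier appearing as both types is an
#' error. Duplicate undirected edges keep the maximum weight with a
#' warning. Node order is lexicographic within each type.
#'
#' @param path one file (with block column) or a named list/vector
#'   `c(gg =, mm =, gm =)` of three files.
#' @param weight_scale forwarded to [multi_omics_network()].
#' @param header does each file start with a header row? The default
#'   `"auto"` treats the first row as a header when its weight field is
#'   not numeric.
#' @return A [multi_omics_network()].
#' @export
read_edge_list <- function(path, weight_scale = "raw_confidence",
                           header = "auto") {
  if (length(path) == 3L) {
    if (is.null(names(path)) || !setequal(names(path), c("gg", "mm", "gm")))
      stop("three files must be named gg, mm and gm")
    edges <- do.call(rbind, lapply(c("gg", "mm", "gm"), function(b) {
      e <- parse_edge_file(path[[b]], header, want_block = FALSE)
      e$block <- b
      e
    }))
  } else if (length(path) == 1L) {
    edges <- parse_edge_file(path, header, want_block = TRUE)
  } else {
    stop("supply one tagged file or three files named gg, mm, gm")
  }
  bad <- !edges$block %in% c("gg", "mm", "gm")
  if (any(bad))
    stop("unknown block tag(s): ",
         paste(unique(edges$block[bad]), collapse = ", "))

  genes <- unique(c(edges$a[edges$block == "gg"],
                    edges$b[edges$block == "gg"],
                    edges$a[edges$block == "gm"]))
  mets <- unique(c(edges$a[edges$block == "mm"],
                   edges$b[edges$block == "mm"],
                   edges$b[edges$block == "gm"]))
  clash <- intersect(genes, mets)
  if (length(clash))
    stop("identifier(s) typed as both gene and metabolite: ",
         paste(utils::head(clash, 5L), collapse = ", "))
  if (!length(genes) || !length(mets))
    stop("the edge lists must mention at least one gene and one metabolite")
  fs <- feature_set(sort(genes), sort(mets))

  fill <- function(block, ids_a, ids_b, symmetric) {
    e <- edges[edges$block == block, , drop = FALSE]
    M <- matrix(0, length(ids_a), length(ids_b),
                dimnames = list(ids_a, ids_b))
    if (!nrow(e)) return(M)
    if (symmetric) {
      # canonical unordered-pair key for duplicate detection
      lo <- pmin(e$a, e$b); hi <- pmax(e$a, e$b)
      key <- paste(lo, hi)
    } else {
      key <- paste(e$a, e$b)
    }
    if (anyDuplicated(key)) {
      warning(sprintf("%d duplicate edge(s) in block %s: keeping max weight",
                      sum(duplicated(key)), block))
      w <- tapply(e$w, key, max)
      first <- !duplicated(key)
      e <- e[first, , drop = FALSE]
      e$w <- as.numeric(w[paste(if (symmetric) pmin(e$a, e$b) else e$a,
                                if (symmetric) pmax(e$a, e$b) else e$b)])
    }
    M[cbind(e$a, e$b)] <- e$w
    if (symmetric) M[cbind(e$b, e$a)] <- e$w
    M
  }
  multi_omics_network(
    fs,
    gg = fill("gg", fs$genes, fs$genes, TRUE),
    mm = fill("mm", fs$metabolites, fs$metabolites, TRUE),
    gm = fill("gm", fs$genes, fs$metabolites, FALSE),
    weight_scale = weight_scale)
}

parse_edge_file <- function(path, header, want_block) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (identical(header, "auto") && length(lines)) {
    first <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
    header <- length(first) >= 3L &&
      is.na(suppressWarnings(as.numeric(first[[3L]])))
  }
  if (isTRUE(header) && length(lines)) lines <- lines[-1L]
  lines_n <- seq_along(lines) + as.integer(header)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; lines_n <- lines_n[keep]
  parts <- strsplit(trimws(lines), "[ \t]+")
  want <- if (want_block) 4L else 3L
  nf <- lengths(parts)
  if (any(nf != want))
    stop(sprintf("malformed row at line %d of %s: expected %d fields, got %d",
                 lines_n[which(nf != want)[1L]], path, want,
                 nf[which(nf != want)[1L]]))
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(w))
    stop(sprintf("non-numeric weight at line %d of %s",
                 lines_n[which(is.na(w))[1L]], path))
  if (any(w < 0))
    stop(sprintf("negative weight at line %d of %s",
                 lines_n[which(w < 0)[1L]], path))
  self <- a == b
  if (any(self))
    stop(sprintf("self-edge at line %d of %s", lines_n[which(self)[1L]],
                 path))
  out <- data.frame(a = a, b = b, w = w, stringsAsFactors = FALSE)
  if (want_block) out$block <- vapply(parts, `[[`, "", 4L)
  out
}

#' Write a multi-omics network as a tagged weighted edge list
#'
#' One row per undirected edge: `node_a`, `node_b`, `weight`, `block`
#' (tab-separated, with header). Symmetric blocks are written once per
#' unordered pair (upper triangle). [read_edge_list()] inverts this
#' exactly for networks whose identifiers are sorted and which have no
#' isolated nodes.
#'
#' @param net a [multi_omics_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "multi_omics_network"))
  block_rows <- function(M, block, symmetric) {
    idx <- if (symmetric) which(upper.tri(M) & M != 0, arr.ind = TRUE)
    else which(M != 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(node_a = rownames(M)[idx[, 1L]],
               node_b = colnames(M)[idx[, 2L]],
               weight = M[idx], block = block, stringsAsFactors = FALSE)
  }
  out <- rbind(block_rows(net$gg, "gg", TRUE),
               block_rows(net$mm, "mm", TRUE),
               block_rows(net$gm, "gm", FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an omics table (samples x features) from delimited text
#'
#' Expects a header row of feature identifiers and a first column of
#' sample identifiers. Feature types come either from explicit identifier
#' vectors (`genes`, `metabolites`) or from identifier prefixes
#' (`gene_prefix`/`met_prefix`). A design is attached by naming the label
#' column (`group_col`, removed from the feature matrix), and for paired
#' designs the pairing column (`pair_col`).
#'
#' @param path delimited text file (tab by default).
#' @param genes,metabolites explicit identifier vectors, or NULL to use
#'   prefixes.
#' @param gene_prefix,met_prefix identifier prefixes used when explicit
#'   vectors are absent.
#' @param design `"none"`, `"two_group"` or `"paired"`.
#' @param group_col,pair_col column names carrying the design.
#' @param sep field separator.
#' @return An [omics_dataset()].
#' @export
read_omics_table <- function(path, genes = NULL, metabolites = NULL,
                             gene_prefix = "g", met_prefix = "m",
                             design = "none", group_col = NULL,
                             pair_col = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a sample-id column plus features")
  sample_ids <- as.character(df[[1L]])
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids in ", path)
  df <- df[, -1L, drop = FALSE]
  group <- pair <- NULL
  if (!is.null(group_col)) {
    if (!group_col %in% colnames(df))
      stop("design column not found: ", group_col)
    group <- df[[group_col]]
    df[[group_col]] <- NULL
  } else if (design != "none") {
    stop("design '", design, "' requires 'group_col'")
  }
  if (!is.null(pair_col)) {
    if (!pair_col %in% colnames(df))
      stop("pairing column not found: ", pair_col)
    pair <- df[[pair_col]]
    df[[pair_col]] <- NULL
  }
  num <- vapply(df, is.numeric, logical(1L))
  if (!all(num))
    stop("non-numeric feature column(s): ",
         paste(utils::head(colnames(df)[!num], 5L), collapse = ", "))
  ids <- colnames(df)
  if (is.null(genes) || is.null(metabolites)) {
    is_g <- startsWith(ids, gene_prefix)
    is_m <- startsWith(ids, met_prefix)
    if (any(is_g & is_m) || any(!is_g & !is_m))
      stop("cannot classify features by prefix; pass 'genes' and ",
           "'metabolites' explicitly")
    genes <- ids[is_g]; metabolites <- ids[is_m]
  } else {
    if (!setequal(ids, c(genes, metabolites)))
      stop("table columns do not match the supplied gene/metabolite lists")
  }
  fs <- feature_set(genes, metabolites)
  X <- as.matrix(df)[, feature_ids(fs), drop = FALSE]
  omics_dataset(X, fs, sample_ids = sample_ids, design = design,
                group = group, pair = pair)
}

#' Write a prioritization result as a tab-separated table
#'
#' Columns: feature, type, pvalue, v0, v, rank, rank_in_type; one row per
#' feature, sorted by combined rank. [read_results()] inverts this.
#'
#' @param result an `association_scores` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "association_scores"))
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a prioritization result written by [write_results()]
#' @param path file written by [write_results()].
#' @return Data frame with the result columns, sorted by rank.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df[order(df$rank), , drop = FALSE]
}

#' Write a study table or evaluation report as tab-separated text
#' @param x data frame (study table, top-k table or IRS report).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
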