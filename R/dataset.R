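#' Assemble a drug-target interaction dataset
#'
#' Bundles the three matrices of a gold-standard drug-target dataset into a
#' validated container: a binary interaction matrix `Y` (drugs in rows,
#' proteins in columns), a drug-drug chemical similarity matrix `S_d`
#' (e.g. SIMCOMP substructure-overlap scores) and a protein-protein sequence
#' similarity matrix `S_p` (e.g. normalized Smith-Waterman scores).
#'
#' Validation enforces: `Y` entries in \{0, 1\} with dimensions matching the
#' id vectors; similarity entries in \[0, 1\]; similarity matrices symmetric
#' (asymmetry up to `1e-6` is repaired by averaging with the transpose,
#' anything larger is rejected); unit diagonals; no duplicate ids.
#'
#' @param Y binary numeric matrix, drugs x proteins.
#' @param S_d numeric drug-drug similarity matrix in \[0, 1\].
#' @param S_p numeric protein-protein similarity matrix in \[0, 1\].
#' @param drug_ids,protein_ids character vectors of identifiers; default to
#'   the dimnames of `Y`, or `d1..dn` / `p1..pn` when absent.
#' @return An object of class `dti_dataset`: a list with elements
#'   `drug_ids`, `protein_ids`, `Y`, `S_d`, `S_p`.
#' @examples
#' Y <- matrix(c(1, 0, 0, 1), 2, 2)
#' ds <- dti_dataset(Y, diag(2), diag(2))
#' ds
#' @export
dti_dataset <- function(Y, S_d, S_p, drug_ids = NULL, protein_ids = NULL) {
  Y <- as.matrix(Y)
  S_d <- as.matrix(S_d)
  S_p <- as.matrix(S_p)
  if (is.null(drug_ids)) {
    drug_ids <- rownames(Y) %||% paste0("d", seq_len(nrow(Y)))
  }
  if (is.null(protein_ids)) {
    protein_ids <- colnames(Y) %||% paste0("p", seq_len(ncol(Y)))
  }
  drug_ids <- as.character(drug_ids)
  protein_ids <- as.character(protein_ids)

  check_ids(drug_ids, "drug_ids")
  check_ids(protein_ids, "protein_ids")
  if (nrow(Y) != length(drug_ids) || ncol(Y) != length(protein_ids)) {
    abort_validation(sprintf(
      "Y is %d x %d but there are %d drug ids and %d protein ids",
      nrow(Y), ncol(Y), length(drug_ids), length(protein_ids)
    ))
  }
  check_binary(Y, "Y")
  S_d <- check_similarity(S_d, length(drug_ids), "S_d")
  S_p <- check_similarity(S_p, length(protein_ids), "S_p")

  dimnames(Y) <- list(drug_ids, protein_ids)
  dimnames(S_d) <- list(drug_ids, drug_ids)
  dimnames(S_p) <- list(protein_ids, protein_ids)

  structure(
    list(drug_ids = drug_ids, protein_ids = protein_ids,
         Y = Y, S_d = S_d, S_p = S_p),
    class = "dti_dataset"
  )
}

#' @export
print.dti_dataset <- function(x, ...) {
  cat(sprintf(
    "<dti_dataset> %d drugs x %d proteins, %d known interactions (density %.3f)\n",
    length(x$drug_ids), length(x$protein_ids), sum(x$Y),
    mean(x$Y)
  ))
  invisible(x)
}

#' @export
dim.dti_dataset <- function(x) c(length(x$drug_ids), length(x$protein_ids))

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "dti_validation_error", ...)
}

check_ids <- function(ids, what) {
  if (anyDuplicated(ids)) {
    abort_validation(sprintf(
      "duplicate identifiers in %s: %s", what,
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  invisible(ids)
}

check_binary <- function(Y, what) {
  bad <- which(!(Y == 0 | Y == 1))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(Y))
    abort_validation(sprintf(
      "%s must be binary; entry [%d, %d] is %g", what, ij[1], ij[2], Y[bad[1]]
    ))
  }
  if (anyNA(Y)) abort_validation(sprintf("%s contains missing values", what))
  invisible(Y)
}

# Symmetrizes small (<= 1e-6) asymmetry from ASCII rounding; rejects larger.
check_similarity <- function(S, n, what, sym_tol = 1e-6) {
  if (nrow(S) != n || ncol(S) != n) {
    abort_validation(sprintf(
      "%s must be %d x %d, got %d x %d", what, n, n, nrow(S), ncol(S)
    ))
  }
  if (anyNA(S) || any(!is.finite(S))) {
    abort_validation(sprintf("%s contains non-finite values", what))
  }
  asym <- max(abs(S - t(S)))
  if (asym > sym_tol) {
    ij <- arrayInd(which.max(abs(S - t(S))), dim(S))
    abort_validation(sprintf(
      "%s is asymmetric beyond tolerance at [%d, %d] (|S - t(S)| = %.3g)",
      what, ij[1], ij[2], asym
    ))
  }
  S <- (S + t(S)) / 2
  if (any(S < 0) || any(S > 1)) {
    bad <- which(S < 0 | S > 1)[1]
    ij <- arrayInd(bad, dim(S))
    abort_validation(sprintf(
      "%s entries must lie in [0, 1]; entry [%d, %d] is %g",
      what, ij[1], ij[2], S[bad]
    ))
  }
  if (any(abs(diag(S) - 1) > sym_tol)) {
    k <- which.max(abs(diag(S) - 1))
    abort_validation(sprintf(
      "%s diagonal must equal 1; entry [%d, %d] is %g", what, k, k, S[k, k]
    ))
  }
  diag(S) <- 1
  S
}

#' Read a gold-standard dataset from tab-delimited matrix files
#'
#' Each file is a TSV matrix: first row holds column ids, first column holds
#' row ids, numeric body. Row/column orders of the similarity matrices are
#' reconciled (reordered) to match the drug and protein order of `Y`.
#'
#' @param path_Y path to the binary drug x protein interaction matrix.
#' @param path_Sd path to the drug x drug chemical similarity matrix.
#' @param path_Sp path to the protein x protein sequence similarity matrix.
#' @return A validated [dti_dataset()].
#' @seealso [write_dti_dataset()] for the inverse.
#' @export
read_dti_dataset <- function(path_Y, path_Sd, path_Sp) {
  Y <- read_matrix_tsv(path_Y)
  S_d <- read_matrix_tsv(path_Sd)
  S_p <- read_matrix_tsv(path_Sp)

  S_d <- align_ids(S_d, rownames(Y), path_Sd, "drug")
  S_p <- align_ids(S_p, colnames(Y), path_Sp, "protein")

  withCallingHandlers(
    dti_dataset(Y, S_d, S_p, rownames(Y), colnames(Y)),
    dti_validation_error = function(e) {
      rlang::abort(
        sprintf("invalid dataset read from %s / %s / %s: %s",
                path_Y, path_Sd, path_Sp, rlang::cnd_message(e)),
        class = "dti_validation_error", parent = e
      )
    }
  )
}

read_matrix_tsv <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("file not found: %s", path))
  }
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    abort_validation(sprintf("non-numeric body in %s", path))
  }
  m
}

align_ids <- function(S, ids, path, side) {
  missing_row <- setdiff(ids, rownames(S))
  extra_row <- setdiff(rownames(S), ids)
  if (length(missing_row) || length(extra_row)) {
    abort_validation(sprintf(
      "%s: %s ids do not match the interaction matrix (missing: %s; unknown: %s)",
      path, side,
      paste(utils::head(missing_row, 3), collapse = ", "),
      paste(utils::head(extra_row, 3), collapse = ", ")
    ))
  }
  if (!identical(colnames(S), rownames(S)) &&
      length(setdiff(ids, colnames(S)))) {
    abort_validation(sprintf("%s: row and column ids disagree", path))
  }
  S[ids, ids, drop = FALSE]
}

#' Write a dataset to three tab-delimited matrix files
#'
#' @param dataset a [dti_dataset()].
#' @param path_Y,path_Sd,path_Sp output paths for the interaction and
#'   similarity matrices.
#' @return The dataset, invisibly.
#' @export
write_dti_dataset <- function(dataset, path_Y, path_Sd, path_Sp) {
  stopifnot(inherits(dataset, "dti_dataset"))
  write_matrix_tsv(dataset$Y, path_Y)
  write_matrix_tsv(dataset$S_d, path_Sd)
  write_matrix_tsv(dataset$S_p, path_Sp)
  invisible(dataset)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  # format(..., digits = 17) keeps doubles exact on round-trip
  body <- as.data.frame(lapply(df[-1], function(x) {
    formatC(x, digits = 17, format = "g")
  }), check.names = FALSE)
  out <- cbind(df[1], body)
  names(out)[1] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rank prediction scores as a tidy edge list
#'
#' Flattens a drug x protein score matrix into one row per pair, sorted by
#' score descending. Ties are broken by drug index then protein index
#' (stable, platform-independent). With `top_k`, only novel pairs (not known
#' interactions in `dataset$Y`) are ranked and the `top_k` highest kept --
#' the "newly predicted interactions with the k highest scores" view used
#' when mining a trained model for candidates.
#'
#' @param scores numeric matrix of prediction scores, drugs x proteins, or a
#'   [dti_fit] object.
#' @param dataset the [dti_dataset()] the scores refer to.
#' @param top_k keep only the `top_k` highest-scoring novel pairs;
#'   `NULL` ranks every pair.
#' @return A tibble with columns `drug_id`, `protein_id`, `score`, `known`.
#' @export
rank_edges <- function(scores, dataset, top_k = NULL) {
  if (inherits(scores, "dti_fit")) scores <- scores$scores
  stopifnot(inherits(dataset, "dti_dataset"))
  n_d <- length(dataset$drug_ids)
  n_p <- length(dataset$protein_ids)
  if (!all(dim(scores) == c(n_d, n_p))) {
    abort_validation("score matrix dimensions do not match the dataset")
  }
  if (any(!is.finite(scores))) {
    abort_validation("score matrix contains non-finite entries")
  }
  edges <- tibble::tibble(
    drug_idx = rep(seq_len(n_d), times = n_p),
    protein_idx = rep(seq_len(n_p), each = n_d),
    drug_id = dataset$drug_ids[.data$drug_idx],
    protein_id = dataset$protein_ids[.data$protein_idx],
    score = as.vector(scores),
    known = as.vector(dataset$Y) == 1
  )
  if (!is.null(top_k)) {
    if (top_k < 1 || top_k > n_d * n_p) {
      abort_validation("top_k must be between 1 and n_drugs * n_proteins")
    }
    edges <- dplyr::filter(edges, !.data$known)
  }
  edges <- dplyr::arrange(edges, dplyr::desc(.data$score),
                          .data$drug_idx, .data$protein_idx)
  if (!is.null(top_k)) edges <- utils::head(edges, top_k)
  dplyr::select(edges, "drug_id", "protein_id", "score", "known")
}

#' Write ranked prediction scores to a TSV edge list
#'
#' @inheritParams rank_edges
#' @param path output path.
#' @return The edge-list tibble, invisibly.
#' @export
write_edges <- function(scores, dataset, path, top_k = NULL) {
  edges <- rank_edges(scores, dataset, top_k = top_k)
  tryCatch(
    readr::write_tsv(edges, path),
    error = function(e) {
      rlang::abort(sprintf("failed to write edge list to %s", path),
                   parent = e)
    }
  )
  invisible(edges)
}
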