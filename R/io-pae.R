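#' Predicted aligned error matrix
#'
#' `pae_matrix` wraps the N x N predicted-aligned-error array (Angstrom)
#' written by structure predictors, plus per-chain bookkeeping: a mapping
#' from chain id to the inclusive global residue index interval it occupies,
#' needed to slice inter-chain blocks.
#'
#' @param values square numeric matrix, finite and non-negative.
#' @param chain_ranges named list, chain id -> integer `c(first, last)`
#'   global residue index (1-based, inclusive), or NULL when unknown.
#' @return An object of class `pae_matrix`.
#' @export
pae_matrix <- function(values, chain_ranges = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("PAE matrix must be square")
  if (!all(is.finite(values))) stop("PAE matrix has non-finite entries")
  if (any(values < 0)) stop("PAE values must be non-negative")
  if (!is.null(chain_ranges)) {
    n <- sum(vapply(chain_ranges, function(r) r[2] - r[1] + 1L, integer(1)))
    if (n != nrow(values))
      stop("chain_ranges cover ", n, " residues but matrix is ",
           nrow(values), " x ", nrow(values))
  }
  structure(list(values = values, chain_ranges = chain_ranges),
            class = "pae_matrix")
}

#' @export
print.pae_matrix <- function(x, ...) {
  cat(sprintf("pae_matrix: %d x %d, mean %.2f A", nrow(x$values),
              ncol(x$values), mean(x$values)))
  if (!is.null(x$chain_ranges))
    cat(", chains:", paste(names(x$chain_ranges), collapse = " "))
  cat("\n")
  invisible(x)
}

#' Read a PAE matrix from a JSON-style file
#'
#' Accepts the predictor-server dialect (an object, or a one-element list of
#' objects, with key `predicted_aligned_error`) or a bare 2-D numeric array.
#' When a companion `model` is supplied, per-chain residue ranges are
#' attached (matrix size must equal the model's residue count).
#'
#' @param path JSON file path.
#' @param model optional [assembly_model] whose residue layout indexes the
#'   matrix.
#' @return A [pae_matrix].
#' @export
read_pae <- function(path, model = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  vals <- payload
  if (is.list(payload) && !is.null(payload$predicted_aligned_error))
    vals <- payload$predicted_aligned_error
  else if (is.list(payload) && is.null(dim(payload)) && length(payload) >= 1 &&
           is.list(payload[[1]]) && !is.null(payload[[1]]$predicted_aligned_error))
    vals <- payload[[1]]$predicted_aligned_error
  if (is.list(vals) && !is.matrix(vals)) {
    lens <- lengths(vals)
    if (length(unique(lens)) != 1L)
      stop("ragged PAE payload: row lengths ", paste(unique(lens), collapse = "/"))
    vals <- do.call(rbind, vals)
  }
  if (!is.numeric(vals) || !is.matrix(vals))
    stop("no square numeric PAE payload found in ", path)
  pae_matrix(vals, chain_ranges = if (!is.null(model)) model_chain_ranges(model))
}

#' Global residue-index ranges of a model's chains
#'
#' Residues are numbered 1..N in model order (chains in model order,
#' residues in (resno, ins) order within each chain), matching how
#' predictors lay out the PAE matrix.
#'
#' @param model an [assembly_model].
#' @return named list, chain id -> integer `c(first, last)`.
#' @export
model_chain_ranges <- function(model) {
  out <- list()
  at <- 0L
  for (ch in chain_ids(model)) {
    n <- length(unique(paste(model$atoms$resno[model$atoms$chain == ch],
                             model$atoms$ins[model$atoms$chain == ch])))
    out[[ch]] <- c(at + 1L, at + n)
    at <- at + n
  }
  out
}

#' Write a PAE matrix to JSON (predictor-server dialect)
#' @param pae a [pae_matrix].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pae <- function(pae, path) {
  stopifnot(inherits(pae, "pae_matrix"))
  jsonlite::write_json(list(predicted_aligned_error = pae$values), path,
                       digits = 6)
  invisible(path)
}
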