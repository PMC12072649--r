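## Descriptor columns taken from the OpenBabel property panel, in fixed
## documented order.
.DESC_PANEL <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")

.requireChemmineOB <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("featurizing SMILES requires the ChemmineOB package")
}

#' Featurize a single drug structure
#'
#' Computes the dual molecular representation: a binary circular
#' substructure (ECFP-type, radius 2 by default) fingerprint OR-folded to
#' `nBits`, and a fixed-order physicochemical descriptor vector (hydrogen
#' bond acceptors/donors, logP, molar refractivity, molecular weight,
#' fluorine count, topological polar surface area). SMILES are
#' canonicalized first so equivalent notations collide.
#'
#' @param smiles a single SMILES string.
#' @param nBits fingerprint length after folding (default 2048).
#' @param radius circular fingerprint radius (default 2).
#' @return list with `fingerprint` (0/1 vector of length `nBits`),
#'   `descriptors` (named numeric), and `canonical` (canonical SMILES).
#'   Errors on unparsable input.
#' @examples
#' \donttest{
#' ftr <- featurizeDrug("CC(=O)Oc1ccccc1C(=O)O")  # aspirin
#' sum(ftr$fingerprint)
#' }
#' @export
featurizeDrug <- function(smiles, nBits = 2048, radius = 2) {
  .requireChemmineOB()
  stopifnot(length(smiles) == 1, nBits >= 1)
  fpName <- paste0("ECFP", 2 * radius)
  res <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, function(m) {
      list(fp = as.numeric(ChemmineOB::fingerprint_OB(list(m), fpName)),
           prop = ChemmineOB::prop_OB(list(m)))
    })[[1]],
    error = function(e) NULL)
  ok <- !is.null(res) && length(res$fp) > 0 && sum(res$fp) > 0 &&
    is.data.frame(res$prop) && nzchar(res$prop$cansmi[1])
  if (!ok) stop("unparsable SMILES: ", smiles)
  fp <- .foldFingerprint(res$fp, nBits)
  desc <- vapply(.DESC_PANEL, function(cn) as.numeric(res$prop[[cn]][1]), numeric(1))
  list(fingerprint = fp, descriptors = desc, canonical = res$prop$cansmi[1])
}

## OR-fold a binary vector down to nBits (wrap-around modulo indexing).
.foldFingerprint <- function(bits, nBits) {
  if (length(bits) <= nBits) {
    out <- numeric(nBits)
    out[seq_along(bits)] <- bits
    return(out)
  }
  idx <- ((seq_along(bits) - 1) %% nBits) + 1
  out <- numeric(nBits)
  on <- idx[bits > 0]
  out[unique(on)] <- 1
  out
}

#' Featurize a drug library
#'
#' Applies [featurizeDrug()] to a `drug_id` / `smiles` table. Unparsable
#' structures are skipped with a warning and reported in the `rejects`
#' slot of the result instead of aborting the run.
#'
#' @param drugs data.frame with columns `drug_id` and `smiles`, or the path
#'   of a TSV file with those columns.
#' @param nBits,radius see [featurizeDrug()].
#' @return a [DrugLibrary-class] with the descriptor scaler fitted on the
#'   successfully featurized set.
#' @export
featurizeLibrary <- function(drugs, nBits = 2048, radius = 2) {
  if (is.character(drugs) && length(drugs) == 1)
    drugs <- read.table(drugs, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("drug_id", "smiles") %in% names(drugs)))
  feats <- lapply(seq_len(nrow(drugs)), function(i)
    tryCatch(featurizeDrug(drugs$smiles[i], nBits, radius),
             error = function(e) NULL))
  ok <- !vapply(feats, is.null, logical(1))
  rejects <- as.character(drugs$drug_id[!ok])
  if (length(rejects))
    warning("skipped unparsable structure(s): ", paste(rejects, collapse = ", "))
  fp <- do.call(rbind, lapply(feats[ok], `[[`, "fingerprint"))
  de <- do.call(rbind, lapply(feats[ok], `[[`, "descriptors"))
  if (is.null(fp)) fp <- matrix(0, 0, nBits)
  if (is.null(de)) de <- matrix(0, 0, length(.DESC_PANEL))
  colnames(de) <- .DESC_PANEL
  drugLibrary(as.character(drugs$drug_id[ok]), fp, de, rejects = rejects)
}

#' Construct a DrugLibrary from precomputed feature matrices
#'
#' @param drugIds character vector of compound ids.
#' @param fingerprints binary matrix, drugs x bits.
#' @param descriptors numeric matrix, drugs x descriptors.
#' @param scaler optional precomputed scaler (list with `mu`, `sigma`);
#'   fitted on `descriptors` when `NULL` and the library has >= 2 drugs.
#' @param rejects character vector of skipped input ids.
#' @return a [DrugLibrary-class].
#' @export
drugLibrary <- function(drugIds, fingerprints, descriptors, scaler = NULL,
                        rejects = character(0)) {
  fingerprints <- as.matrix(fingerprints)
  descriptors <- as.matrix(descriptors)
  rownames(fingerprints) <- rownames(descriptors) <- drugIds
  if (is.null(scaler)) {
    scaler <- if (length(drugIds) >= 2) fitScaler(descriptors) else list()
  }
  std <- if (length(scaler)) applyScaler(scaler, descriptors)
         else matrix(0, nrow(descriptors), ncol(descriptors),
                     dimnames = dimnames(descriptors))
  new("DrugLibrary", drugIds = as.character(drugIds),
      fingerprints = fingerprints, descriptors = descriptors,
      descriptorsStd = std, scaler = scaler, rejects = rejects)
}

#' @describeIn drugLibrary compound identifiers.
#' @param lib a `DrugLibrary`.
#' @export
drugIds <- function(lib) lib@drugIds

#' @describeIn drugLibrary binary fingerprint matrix.
#' @export
drugFingerprints <- function(lib) lib@fingerprints

#' @describeIn drugLibrary standardized descriptor matrix.
#' @export
drugDescriptors <- function(lib) lib@descriptorsStd

setMethod("show", "DrugLibrary", function(object) {
  cat(sprintf("DrugLibrary: %d drugs, %d fingerprint bits, %d descriptors\n",
              length(object@drugIds), ncol(object@fingerprints),
              ncol(object@descriptors)))
  if (length(object@rejects))
    cat(sprintf("  %d rejected input(s)\n", length(object@rejects)))
})

#' Fit / apply the column-wise descriptor standardizer
#'
#' `fitScaler` records the dataset-wise column means and sample standard
#' deviations; `applyScaler` maps descriptors to z-scores
#' `(d - mu) / sigma`. Columns with zero variance are uninformative and
#' map to 0.
#'
#' @param X numeric matrix (drugs x descriptors) with >= 2 rows.
#' @return `fitScaler`: list with `mu` and `sigma`; `applyScaler`: matrix
#'   (or vector) of z-scores.
#' @export
fitScaler <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("fitting the scaler requires at least 2 drugs")
  list(mu = colMeans(X), sigma = apply(X, 2, sd))
}

#' @rdname fitScaler
#' @param scaler a fitted scaler.
#' @param d descriptor matrix or single vector of matching width.
#' @export
applyScaler <- function(scaler, d) {
  vec <- is.null(dim(d))
  X <- if (vec) matrix(d, nrow = 1) else as.matrix(d)
  if (ncol(X) != length(scaler$mu))
    stop(sprintf("descriptor width %d does not match scaler width %d",
                 ncol(X), length(scaler$mu)))
  sig <- scaler$sigma
  zero <- sig < .Machine$double.eps * 100
  sig[zero] <- 1
  Z <- sweep(sweep(X, 2, scaler$mu, "-"), 2, sig, "/")
  Z[, zero] <- 0
  if (vec) Z[1, ] else Z
}
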