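#' Screen a drug library against the selected target genes
#'
#' Runs Monte-Carlo-dropout prediction for every (drug, target gene) pair,
#' processing the library in drug batches. One record per pair is
#' returned with the mean score, MC variance (epistemic), mean aleatoric
#' uncertainty and the derived probability percentage; deterministic
#' given `seed`.
#'
#' @param model a trained [DTIModel-class].
#' @param lib a [DrugLibrary-class].
#' @param targets named list of per-community gene vectors (from
#'   [selectTargets()]) or a character vector of genes.
#' @param batch drug batch size (default 64).
#' @param T Monte-Carlo passes per batch.
#' @param seed RNG seed.
#' @return data.frame with columns `drug_id`, `gene_id`, `cluster`,
#'   `sbar`, `sigma2`, `u`, `probability_pct`.
#' @export
screenLibrary <- function(model, lib, targets, batch = 64,
                          T = model@config$mcPasses, seed = 1L) {
  if (is.list(targets)) {
    cl <- rep(names(targets), lengths(targets))
    genes <- unlist(targets, use.names = FALSE)
  } else {
    genes <- as.character(targets)
    mem <- apply(model@clusterOneHot, 1, which.max) - 1L
    cl <- as.character(mem[match(genes, model@genes)])
  }
  if (!length(genes)) stop("empty target set")
  nD <- length(lib@drugIds)
  out <- vector("list", ceiling(nD / batch))
  bi <- 0
  for (start in seq(1, nD, by = batch)) {
    idx <- start:min(start + batch - 1, nD)
    pairsD <- rep(idx, each = length(genes))
    pairsG <- rep(genes, length(idx))
    pr <- predictMC(model, lib@fingerprints[pairsD, , drop = FALSE],
                    lib@descriptorsStd[pairsD, , drop = FALSE], pairsG,
                    T = T, seed = seed + bi)
    bi <- bi + 1
    out[[bi]] <- data.frame(
      drug_id = lib@drugIds[pairsD], gene_id = pairsG,
      cluster = rep(cl, length(idx)), sbar = pr$sbar, sigma2 = pr$sigma2,
      u = pr$u, stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out)
  rec$probability_pct <- 100 * rec$sbar
  rownames(rec) <- NULL
  rec
}

#' Normalize screening scores per target gene
#'
#' Adds, per target gene, the library z-score of the raw (mean) score
#' (population standard deviation) and the empirical rank percentile
#' `100 * (N - rank_index) / N` where the best score has rank index 0
#' (percentile 100). z is invariant to affine rescaling of the raw
#' scores; a gene with zero score variance gets z = 0 with a warning.
#'
#' @param records screening records from [screenLibrary()] (needs
#'   `gene_id` and `sbar`).
#' @return the records with `z` and `percentile` columns added.
#' @export
normalizeScores <- function(records) {
  if (nrow(records) < 2) stop("normalization requires at least 2 records")
  records$z <- NA_real_
  records$percentile <- NA_real_
  for (gn in unique(records$gene_id)) {
    i <- which(records$gene_id == gn)
    x <- records$sbar[i]
    mu <- mean(x)
    sdp <- sqrt(mean((x - mu)^2))
    if (sdp < .Machine$double.eps * 100) {
      warning("zero score variance for gene ", gn, "; z set to 0")
      records$z[i] <- 0
    } else records$z[i] <- (x - mu) / sdp
    ord <- order(-x, records$drug_id[i])
    rankIdx <- integer(length(i))
    rankIdx[ord] <- seq_along(i) - 1L
    records$percentile[i] <- 100 * (length(i) - rankIdx) / length(i)
  }
  records
}

## Total per-record uncertainty: aleatoric plus the MC standard
## deviation, capped at 1.
.totalUncertainty <- function(records) {
  pmin(records$u + sqrt(records$sigma2), 1)
}

#' Filter screening records by total uncertainty
#'
#' Keeps records with total uncertainty (aleatoric + MC standard
#' deviation, capped at 1) below `tau`. If fewer than `minPass` distinct
#' drugs survive, the filter is re-applied at the relaxed threshold.
#'
#' @param records screening records.
#' @param tau primary uncertainty threshold (default 0.5).
#' @param tauRelaxed fallback threshold (default 0.7).
#' @param minPass minimum surviving drug count before relaxing.
#' @return list with `records` (filtered), `tau` (threshold applied) and
#'   `relaxed` (logical).
#' @export
filterByUncertainty <- function(records, tau = 0.5, tauRelaxed = 0.7,
                                minPass = 10) {
  if (!nrow(records))
    return(list(records = records, tau = tau, relaxed = FALSE))
  tu <- .totalUncertainty(records)
  keep <- tu < tau
  if (length(unique(records$drug_id[keep])) < minPass) {
    keep <- tu < tauRelaxed
    return(list(records = records[keep, , drop = FALSE], tau = tauRelaxed,
                relaxed = TRUE))
  }
  list(records = records[keep, , drop = FALSE], tau = tau, relaxed = FALSE)
}

#' Rank drugs by uncertainty-penalized mean affinity
#'
#' `Rank(d) = mean over targets of sbar - lambdaPenalty * mean over
#' targets of sqrt(u^2 + sigma^2)`: the mean interaction affinity minus a
#' penalty on the combined (aleatoric + epistemic) uncertainty. Sorted
#' descending; ties broken by lower total uncertainty, then by drug id.
#'
#' @param records screening records covering every (drug, target) pair.
#' @param targets character vector of target genes (default: all genes in
#'   `records`).
#' @param lambdaPenalty uncertainty penalty weight (default 1).
#' @return data.frame `drug_id`, `affinity`, `totalUncertainty`,
#'   `rankScore`, `rank`.
#' @export
rankDrugs <- function(records, targets = unique(records$gene_id),
                      lambdaPenalty = 1.0) {
  rec <- records[records$gene_id %in% targets, , drop = FALSE]
  drugs <- unique(rec$drug_id)
  tab <- table(rec$drug_id)
  missing <- names(tab)[tab < length(targets)]
  if (length(missing))
    stop("missing (drug, target) pair(s) for: ",
         paste(head(missing, 5), collapse = ", "))
  aff <- tapply(rec$sbar, rec$drug_id, mean)
  unc <- tapply(sqrt(rec$u^2 + rec$sigma2), rec$drug_id, mean)
  drugs <- names(aff)
  score <- as.numeric(aff) - lambdaPenalty * as.numeric(unc)
  ord <- order(-score, as.numeric(unc), drugs)
  data.frame(drug_id = drugs[ord], affinity = as.numeric(aff)[ord],
             totalUncertainty = as.numeric(unc)[ord],
             rankScore = score[ord], rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Extract multi-target (polypharmacology) candidates
#'
#' Returns drugs whose library z-score exceeds `zThreshold` for at least
#' two target genes lying in at least two distinct network clusters — the
#' signature of a candidate acting on separate disease modules. For each
#' such drug the best gene per qualifying cluster is reported (top two
#' clusters by z), with the mean z, percentile, probability and total
#' uncertainty of that target pair.
#'
#' @param records normalized screening records (needs `z`, `percentile`,
#'   `cluster`).
#' @param zThreshold z-score cut (default 2.8).
#' @return data.frame `drug_id`, `targets`, `z_score`, `percentile`,
#'   `probability_pct`, `uncertainty`; zero rows when no candidate
#'   qualifies.
#' @export
findMultitarget <- function(records, zThreshold = 2.8) {
  if (is.null(records$z)) stop("records must be normalized first")
  hits <- records[records$z > zThreshold, , drop = FALSE]
  out <- data.frame(drug_id = character(0), targets = character(0),
                    z_score = numeric(0), percentile = numeric(0),
                    probability_pct = numeric(0), uncertainty = numeric(0),
                    stringsAsFactors = FALSE)
  for (dr in unique(hits$drug_id)) {
    h <- hits[hits$drug_id == dr, , drop = FALSE]
    if (length(unique(h$gene_id)) < 2 || length(unique(h$cluster)) < 2) next
    ## best gene per cluster, then the two clusters with the highest z
    best <- do.call(rbind, lapply(split(h, h$cluster), function(x)
      x[which.max(x$z), , drop = FALSE]))
    best <- best[order(-best$z), , drop = FALSE][1:2, ]
    out <- rbind(out, data.frame(
      drug_id = dr, targets = paste(best$gene_id, collapse = ";"),
      z_score = mean(best$z), percentile = mean(best$percentile),
      probability_pct = mean(best$probability_pct),
      uncertainty = mean(.totalUncertainty(best)),
      stringsAsFactors = FALSE))
  }
  out[order(-out$z_score), , drop = FALSE]
}
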