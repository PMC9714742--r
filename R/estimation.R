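# Replication-coefficient estimation from two-step translation/replication
# assays, plus the Hamming-distance utility for representative sequences.

#' Common-log fold value of a replication assay
#'
#' The raw measurement behind coefficient estimation: the common logarithm
#' of the concentration increase ratio over the replication step.
#'
#' @param conc_start,conc_end concentrations before and after the
#'   replication step (any common unit); both must be positive.
#' @return `log10(conc_end / conc_start)`, vectorized.
#' @export
fold_value <- function(conc_start, conc_end) {
  if (any(conc_start <= 0) || any(conc_end <= 0))
    stop("concentrations must be positive to form a fold value",
         call. = FALSE)
  log10(conc_end / conc_start)
}

#' Read a fold-table CSV
#'
#' Expected columns: `rna_I` (the species whose replicase was translated in
#' the first step), `rna_II` (the added template), `measured` (which of the
#' two was quantified), `replicate`, `conc_0h`, `conc_1h`.
#'
#' @param path CSV file path.
#' @return A tibble with the input columns plus `fold`.
#' @export
read_fold_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("rna_I", "rna_II", "measured", "replicate", "conc_0h", "conc_1h")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("fold table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$fold <- fold_value(df$conc_0h, df$conc_1h)
  tibble::as_tibble(df)
}

mean_fold <- function(folds, i, j, h) {
  v <- folds$fold[folds$rna_I == i & folds$rna_II == j & folds$measured == h]
  if (!length(v)) return(c(mean = NA_real_, sd = NA_real_, n = 0))
  c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
    n = length(v))
}

#' Estimate replication coefficients from assay fold values
#'
#' Self-replication coefficients are the self-assay fold values,
#' `k_ii^H = v_iii` (species `i` as both RNA I and II, measuring `i`).
#' Cross coefficients remove the competition between RNA I and RNA II by
#' normalizing with the fold value of the replicase's own RNA in the same
#' reaction:
#' \deqn{k_{ij} = k_{ii}^H \, v_{ij}^{j} / v_{ij}^{i}.}
#' Replicate measurements enter through their mean; full precision is kept
#' (tables conventionally print one decimal, but downstream simulations
#' should not inherit presentation rounding).
#'
#' @param folds a tibble as returned by [read_fold_table()] (columns
#'   `rna_I`, `rna_II`, `measured`, `fold`; `replicate` optional).
#' @param roles named character vector of roles. By default species that
#'   ever provided replicase (appear as `rna_I`) are hosts and the rest are
#'   parasites.
#' @return A [coefficient_matrix()] (rows = replicase, columns = template)
#'   with attribute `"details"`: a tibble of per-pair means, standard
#'   deviations and replicate counts. A zero competitive fold `v_iji`
#'   leaves the coefficient `NA` with a warning; negative folds propagate
#'   with a warning.
#' @export
estimate_coefficients <- function(folds, roles = NULL) {
  if (!"fold" %in% names(folds)) {
    folds <- folds  # allow pre-computed tables
    folds$fold <- fold_value(folds$conc_0h, folds$conc_1h)
  }
  species <- unique(c(folds$rna_I, folds$rna_II, folds$measured))
  if (is.null(roles)) {
    roles <- setNames(ifelse(species %in% unique(folds$rna_I),
                             "host", "parasite"), species)
  }
  species <- names(roles)
  hosts <- species[roles == "host"]
  k <- matrix(0, length(species), length(species),
              dimnames = list(species, species))
  details <- list()
  for (i in hosts) {
    self <- mean_fold(folds, i, i, i)
    if (is.na(self["mean"]))
      stop("self-assay folds (rna_I = rna_II = measured = ", i,
           ") are required", call. = FALSE)
    k[i, i] <- self[["mean"]]
    details[[length(details) + 1]] <-
      data.frame(replicase = i, template = i, k = self[["mean"]],
                 fold_sd = self[["sd"]], n_replicates = self[["n"]])
    for (j in setdiff(species, i)) {
      vijj <- mean_fold(folds, i, j, j)
      viji <- mean_fold(folds, i, j, i)
      if (is.na(vijj["mean"]) || is.na(viji["mean"])) next
      if (viji[["mean"]] == 0) {
        warning("competitive fold v_", i, j, "^", i,
                " is zero; coefficient k(", i, " -> ", j, ") undefined",
                call. = FALSE)
        kij <- NA_real_
      } else {
        kij <- k[i, i] * vijj[["mean"]] / viji[["mean"]]
        if (kij < 0)
          warning("negative estimated coefficient k(", i, " -> ", j, ")",
                  call. = FALSE)
      }
      k[i, j] <- kij
      details[[length(details) + 1]] <-
        data.frame(replicase = i, template = j, k = kij,
                   fold_sd = vijj[["sd"]], n_replicates = vijj[["n"]])
    }
  }
  out <- coefficient_matrix(k, roles)
  attr(out, "details") <- tibble::as_tibble(do.call(rbind, details))
  out
}

#' Hamming distance between two equal-length sequences
#'
#' Counts mismatched positions. Sequences containing indels must be handled
#' upstream (this is an alignment-free comparison of equal-length
#' sequences); unequal lengths are an error.
#'
#' @param seq_a,seq_b character scalars (nucleotide sequences); case is
#'   ignored.
#' @return Integer count of mismatching positions.
#' @export
hamming_distance <- function(seq_a, seq_b) {
  a <- charToRaw(toupper(seq_a))
  b <- charToRaw(toupper(seq_b))
  if (length(a) != length(b))
    stop("sequences differ in length (", length(a), " vs ", length(b),
         "); align or trim them first - this comparison is alignment-free",
         call. = FALSE)
  sum(a != b)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta_sequences <- function(path) {
  seqs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  setNames(toupper(vapply(seqs, `[[`, "", 1L)), names(seqs))
}
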