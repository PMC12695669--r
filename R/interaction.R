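# Construction of the marginal-epistasis design E_t: elementwise products of
# the target SNP's standardized genotype with every retained SNP, honoring
# exclusions (the target's LD block, the target itself) and scope
# restrictions (genome / local / distal), with an optional row permutation
# used as a negative control.

#' Specify the interaction component for a target SNP
#'
#' @param target_index index of the target SNP in the analysis panel
#' @param excluded_indices SNP indices excluded from interaction pairing
#'   (the target's LD block; the target itself is always added)
#' @param scope `"genome"` pairs the target with all retained SNPs,
#'   `"local"` only with SNPs on the target's chromosome, `"distal"` only
#'   with SNPs on other chromosomes
#' @param rescale_columns if TRUE, each product column is re-centered and
#'   rescaled to sum of squares N. Off by default: the interaction prior is
#'   written over the raw product columns.
#' @param permutation optional row permutation applied to every interaction
#'   block (negative control); see [permutation_from_seed()]
#' @return an `interaction_spec`
#' @export
interaction_spec <- function(target_index, excluded_indices = integer(),
                             scope = c("genome", "local", "distal"),
                             rescale_columns = FALSE, permutation = NULL) {
  scope <- match.arg(scope)
  structure(list(target_index = as.integer(target_index),
                 excluded_indices = sort(unique(as.integer(
                   c(excluded_indices, target_index)))),
                 scope = scope, rescale_columns = isTRUE(rescale_columns),
                 permutation = permutation),
            class = "interaction_spec")
}

#' SNP indices retained by an interaction spec
#'
#' @param spec an [interaction_spec()]
#' @param panel_meta per-SNP metadata of the analysis panel
#' @return integer indices of the SNPs paired with the target
#' @export
interaction_columns <- function(spec, panel_meta) {
  idx <- setdiff(seq_len(nrow(panel_meta)), spec$excluded_indices)
  if (spec$scope != "genome") {
    tchr <- .chr_norm(panel_meta$chr[spec$target_index])
    on_chr <- .chr_norm(panel_meta$chr[idx]) == tchr
    idx <- if (spec$scope == "local") idx[on_chr] else idx[!on_chr]
  }
  idx
}

#' Build one block of the interaction design
#'
#' Column j of the output is the elementwise product of the target SNP's
#' standardized genotype with standardized SNP j of the block. Product
#' columns are not re-standardized unless the spec asks for it; their means
#' are in general nonzero and downstream code must not assume otherwise.
#'
#' @param x_target standardized genotype column of the target SNP
#' @param block N x b matrix of standardized genotypes to pair with
#' @param spec an [interaction_spec()]; its permutation, if any, is applied
#'   to the rows of the result
#' @return N x b numeric matrix
#' @export
build_interaction_block <- function(x_target, block, spec) {
  if (length(spec$excluded_indices) == 0L ||
      !(spec$target_index %in% spec$excluded_indices))
    stop("target SNP must be in the exclusion set (guards double-counting)")
  if (sum(x_target^2) == 0)
    stop("target column is identically zero; not a standardized genotype")
  E <- as.matrix(block) * x_target
  if (spec$rescale_columns) E <- standardize_block(E)
  if (!is.null(spec$permutation)) E <- E[spec$permutation, , drop = FALSE]
  E
}

#' Draw a reproducible row permutation
#'
#' Used to permute the rows of the interaction design relative to the
#' phenotype and the additive design: under the model, permutation destroys
#' the alignment between E_t and y, so a permuted fit is a negative control
#' whose interaction variance component should be near zero.
#'
#' @param n number of samples
#' @param seed integer seed
#' @return an integer permutation of `1:n`
#' @export
permutation_from_seed <- function(n, seed) {
  rng <- .seeded_rng(seed, "permute")
  rng(sample.int(n))
}

# Returns a function evaluating expressions under a private RNG stream
# derived from (seed, label). The stream continues across calls and never
# disturbs the caller's RNG state. Distinct seeds are spaced by 1000 so
# label offsets (< 1000) cannot collide across seeds.
.seeded_rng <- function(seed, label = "") {
  offset <- sum(utf8ToInt(label)) %% 1000L
  derived <- (abs(as.integer(seed)) %% 2000000L) * 1000L + offset
  state <- NULL
  function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(state)) set.seed(derived)
    else assign(".Random.seed", state, envir = globalenv())
    result <- expr
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    result
  }
}
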