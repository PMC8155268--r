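#' Specification for a simulated expression dataset
#'
#' Single-latent-factor-per-module model: gene `g` in module `m` is
#' `x_g = rho_g * e_m + sqrt(1 - rho_g^2) * eps_g` with `e_m` and `eps_g`
#' standard normal per sample, so two members with loadings `rho_i`, `rho_j`
#' have expected correlation `rho_i * rho_j`. The first gene of every module
#' carries the maximum loading and is the planted hub. Background genes are
#' pure noise.
#'
#' @param n_samples Number of samples.
#' @param module_sizes Integer vector of module gene counts.
#' @param loading_range `(rho_min, rho_max)` in `(0, 1]`.
#' @param n_background Number of noise genes.
#' @param noise_sd Standard deviation of the idiosyncratic noise (1 keeps unit
#'   gene variance and the `rho_i * rho_j` correlation exactly).
#' @param seed RNG seed for reproducibility.
#' @return Validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 100L, module_sizes = rep(50L, 5L),
                           loading_range = c(0.5, 0.9), n_background = 500L,
                           noise_sd = 1, seed = 20210513L) {
  stopifnot(n_samples >= 3L, all(module_sizes >= 1L), n_background >= 0L,
            length(loading_range) == 2L,
            loading_range[1L] > 0, loading_range[1L] <= loading_range[2L],
            loading_range[2L] <= 1, noise_sd > 0)
  structure(list(n_samples = as.integer(n_samples),
                 module_sizes = as.integer(module_sizes),
                 loading_range = as.numeric(loading_range),
                 n_background = as.integer(n_background),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# emit one matrix given per-gene module assignment and loadings;
# assumes the RNG state is already set by the caller
emit_matrix <- function(assignment, loadings, n_samples, noise_sd, sample_prefix) {
  genes <- names(assignment)
  x <- matrix(0, length(genes), n_samples,
              dimnames = list(genes, sprintf("%s%03d", sample_prefix, seq_len(n_samples))))
  for (mm in setdiff(unique(assignment), "grey")) {
    e <- stats::rnorm(n_samples)
    for (g in names(assignment)[assignment == mm]) {
      rho <- loadings[[g]]
      x[g, ] <- rho * e + sqrt(1 - rho^2) * stats::rnorm(n_samples, sd = noise_sd)
    }
  }
  bg <- names(assignment)[assignment == "grey"]
  if (length(bg) > 0L) {
    x[bg, ] <- stats::rnorm(length(bg) * n_samples, sd = noise_sd)
  }
  x
}

# draw loadings for one module: hub (first gene) at rho_max, rest uniform
draw_loadings <- function(size, loading_range) {
  rho <- stats::runif(size, loading_range[1L], loading_range[2L])
  rho[1L] <- loading_range[2L]
  rho
}

#' Simulate an expression matrix with planted modules
#'
#' @param spec A [synthetic_spec()].
#' @return List with `expression` (gene x sample matrix) and `truth`: list
#'   with `partition` (named gene -> "mod1".../"grey"), `loadings` (named,
#'   NA for background) and `hubs` (one planted hub gene per module).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_mod_genes <- sum(spec$module_sizes)
  genes <- sprintf("g%05d", seq_len(n_mod_genes + spec$n_background))
  mod_labels <- if (length(spec$module_sizes) > 0L) {
    rep(paste0("mod", seq_along(spec$module_sizes)), spec$module_sizes)
  } else character(0)
  assignment <- stats::setNames(
    c(mod_labels, rep("grey", spec$n_background)), genes)
  loadings <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (i in seq_along(spec$module_sizes)) {
    idx <- names(assignment)[assignment == paste0("mod", i)]
    loadings[idx] <- draw_loadings(spec$module_sizes[i], spec$loading_range)
  }
  x <- emit_matrix(assignment, loadings, spec$n_samples, spec$noise_sd, "s")
  hubs <- vapply(paste0("mod", seq_along(spec$module_sizes)),
                 function(mm) names(assignment)[assignment == mm][1L], character(1L))
  list(expression = x,
       truth = list(partition = assignment, loadings = loadings, hubs = hubs))
}

#' Simulate a pair of datasets sharing a subset of modules
#'
#' The first `n_shared_modules` modules use identical gene identifiers and
#' loadings in both datasets (sample draws are independent, emulating two
#' studies of partly conserved biology). Each remaining module is unique to
#' its dataset: its genes appear in the partner dataset too, but there as
#' pure background noise — a hub on one side, peripheral on the other.
#' Background identifiers are shared up to the smaller background count.
#'
#' @param spec_a,spec_b [synthetic_spec()] objects.
#' @param n_shared_modules Number of leading modules conserved between the
#'   datasets; at most `min` of the two module counts.
#' @param seed Seed governing the whole paired draw (overrides the specs').
#' @return List with elements `a` and `b`, each as [simulate_expression()],
#'   plus per-truth `shared` flags (named logical per module).
#' @export
simulate_paired <- function(spec_a, spec_b, n_shared_modules, seed = spec_a$seed) {
  stopifnot(inherits(spec_a, "synthetic_spec"), inherits(spec_b, "synthetic_spec"),
            n_shared_modules >= 0L,
            n_shared_modules <= min(length(spec_a$module_sizes),
                                    length(spec_b$module_sizes)))
  shared_sizes <- spec_a$module_sizes[seq_len(n_shared_modules)]
  if (n_shared_modules > 0L &&
      !identical(shared_sizes, spec_b$module_sizes[seq_len(n_shared_modules)])) {
    stop("shared modules must have identical sizes in both specs")
  }
  uniq_a <- spec_a$module_sizes[-seq_len(n_shared_modules)]
  uniq_b <- spec_b$module_sizes[-seq_len(n_shared_modules)]
  if (n_shared_modules == 0L) { uniq_a <- spec_a$module_sizes; uniq_b <- spec_b$module_sizes }

  n_total <- sum(shared_sizes) + sum(uniq_a) + sum(uniq_b) +
    max(spec_a$n_background, spec_b$n_background)
  ids <- sprintf("g%05d", seq_len(n_total))
  take <- function(n) { out <- ids[seq_len(n)]; ids <<- ids[-seq_len(n)]; out }
  shared_genes <- lapply(shared_sizes, take)
  ua_genes <- lapply(uniq_a, take)
  ub_genes <- lapply(uniq_b, take)
  bg_pool <- ids

  set.seed(seed)
  shared_loadings <- lapply(shared_sizes, draw_loadings, spec_a$loading_range)
  ua_loadings <- lapply(uniq_a, draw_loadings, spec_a$loading_range)
  ub_loadings <- lapply(uniq_b, draw_loadings, spec_b$loading_range)

  build <- function(spec, own_genes, own_loadings, partner_genes, bg_n, prefix) {
    mods <- c(shared_genes, own_genes)
    loadl <- c(shared_loadings, own_loadings)
    genes <- c(unlist(mods), unlist(partner_genes), bg_pool[seq_len(bg_n)])
    assignment <- stats::setNames(rep("grey", length(genes)), genes)
    loadings <- stats::setNames(rep(NA_real_, length(genes)), genes)
    for (i in seq_along(mods)) {
      assignment[mods[[i]]] <- paste0("mod", i)
      loadings[mods[[i]]] <- loadl[[i]]
    }
    x <- emit_matrix(assignment, loadings, spec$n_samples, spec$noise_sd, prefix)
    labels <- paste0("mod", seq_along(mods))
    hubs <- vapply(mods, `[[`, character(1L), 1L)
    names(hubs) <- labels
    shared <- stats::setNames(seq_along(mods) <= length(shared_genes), labels)
    list(expression = x,
         truth = list(partition = assignment, loadings = loadings,
                      hubs = hubs, shared = shared))
  }
  a <- build(spec_a, ua_genes, ua_loadings, ub_genes, spec_a$n_background, "a")
  b <- build(spec_b, ub_genes, ub_loadings, ua_genes, spec_b$n_background, "b")
  list(a = a, b = b)
}

#' Gene sets of the planted modules
#'
#' One set per true (non-background) module, for enrichment recovery checks.
#'
#' @param truth Ground-truth list from the simulator.
#' @return `gene_set_collection` with one set per planted module.
#' @export
truth_gene_sets <- function(truth) {
  mods <- setdiff(unique(unclass(truth$partition)), "grey")
  sets <- lapply(mods, function(mm) names(truth$partition)[truth$partition == mm])
  names(sets) <- mods
  structure(sets,
            descriptions = stats::setNames(rep("planted module", length(mods)), mods),
            class = "gene_set_collection")
}
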