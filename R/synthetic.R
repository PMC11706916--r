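#' Default synthetic group profiles
#'
#' Parameter sets for the synthetic assemblage generator. The profiles are
#' synthetic — the real ethnographic compositions are not reproduced here —
#' and encode only the qualitative processing logic of the attribute scheme:
#'
#' * group 1 (winnowing by-product): enriched in light seeds, `SFL`/`SHL`;
#' * group 2 (coarse sieve by-product): enriched in headed seeds retained by
#'   the coarse mesh, `BHH`/`SHH`;
#' * group 3 (fine sieve by-product): enriched in small seeds that pass the
#'   fine mesh, `SFH`/`SFL`;
#' * group 4 (fine sieve product): enriched in big seeds retained with the
#'   grain, `BFH`/`BHH`.
#'
#' Each profile gives a composition over the six codes, the number of taxa
#' carrying each code, the expected seeds per sample and a Dirichlet
#' concentration controlling sample-to-sample overdispersion (higher =
#' tighter groups).
#'
#' @param separation `"high"` (concentrated, well-separated groups — the
#'   default stated testing world) or `"moderate"`.
#' @return Named list of four `group_profile` lists with elements `label`,
#'   `weights` (named over [ATTRIBUTE_CODES]), `taxa_per_code`,
#'   `seeds_per_sample`, `concentration`.
#' @export
default_group_profiles <- function(separation = c("high", "moderate")) {
  separation <- match.arg(separation)
  conc <- if (separation == "high") 60 else 12
  w <- function(BHH = 1, BFH = 1, SHH = 1, SHL = 1, SFH = 1, SFL = 1) {
    v <- c(BHH = BHH, BFH = BFH, SHH = SHH, SHL = SHL, SFH = SFH, SFL = SFL)
    v / sum(v)
  }
  profile <- function(label, weights) {
    list(label = label, weights = weights, taxa_per_code = 2L,
         seeds_per_sample = 120, concentration = conc)
  }
  list(
    `1` = profile(1L, w(SFL = 40, SHL = 25)),
    `2` = profile(2L, w(BHH = 40, SHH = 25)),
    `3` = profile(3L, w(SFH = 40, SFL = 25)),
    `4` = profile(4L, w(BFH = 40, BHH = 25))
  )
}

# taxon pool shared by all synthetic tables: taxa_per_code taxa per code,
# named <code>_t<j>
synthetic_taxa <- function(taxa_per_code = 2L) {
  codes <- rep(ATTRIBUTE_CODES, each = taxa_per_code)
  ids <- paste0(codes, "_t", rep(seq_len(taxa_per_code),
                                 times = length(ATTRIBUTE_CODES)))
  list(ids = ids, codes = codes)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

# draw one sample's taxon counts from a profile (compound multinomial by
# default); contamination mixes a fraction of seeds from another profile
draw_sample <- function(profile, taxa, overdispersed = TRUE,
                        contamination = 0, contamination_weights = NULL) {
  alpha_taxon <- profile$weights[taxa$codes] /
    tabulate(match(taxa$codes, ATTRIBUTE_CODES),
             length(ATTRIBUTE_CODES))[match(taxa$codes, ATTRIBUTE_CODES)]
  comp <- if (overdispersed) {
    rdirichlet1(alpha_taxon * profile$concentration)
  } else {
    alpha_taxon / sum(alpha_taxon)
  }
  if (contamination > 0) {
    cw <- contamination_weights[taxa$codes]
    cw <- cw / sum(cw)
    comp <- (1 - contamination) * comp + contamination * cw
  }
  n <- stats::rpois(1L, profile$seeds_per_sample)
  if (n < 1L) n <- 1L
  stats::rmultinom(1L, n, comp)[, 1L]
}

#' Generate a synthetic ethnographic reference table
#'
#' Draws integer weed-seed counts for `n_per_group` samples from each of the
#' four group profiles over a shared synthetic taxon pool. Per sample, a
#' taxon composition is drawn from the group's Dirichlet (compound
#' multinomial, giving realistic overdispersion; set
#' `overdispersed = FALSE` for a plain multinomial), then counts are drawn
#' with a Poisson total around the profile's expected seeds per sample.
#'
#' @param profiles list of four group profiles
#'   ([default_group_profiles()]).
#' @param n_per_group samples per group (>= 2).
#' @param seed integer RNG seed (required, for reproducibility).
#' @param overdispersed draw per-sample compositions from a Dirichlet
#'   (default) rather than using the profile composition directly.
#' @return list with `table` (a [count_table()] of weed taxa, all coded) and
#'   `groups` (integer label per sample).
#' @export
generate_reference <- function(profiles = default_group_profiles(),
                               n_per_group = 25, seed,
                               overdispersed = TRUE) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_per_group < 2L) stop("n_per_group must be >= 2", call. = FALSE)
  for (pf in profiles)
    if (all(pf$weights <= 0))
      stop("degenerate profile: all-zero weights", call. = FALSE)
  set.seed(seed)
  taxa <- synthetic_taxa(profiles[[1L]]$taxa_per_code)
  counts <- NULL
  groups <- integer()
  ids <- character()
  for (g in seq_along(profiles)) {
    for (i in seq_len(n_per_group)) {
      counts <- cbind(counts, draw_sample(profiles[[g]], taxa, overdispersed))
      groups <- c(groups, profiles[[g]]$label)
      ids <- c(ids, sprintf("eth_g%d_s%02d", profiles[[g]]$label, i))
    }
  }
  dimnames(counts) <- list(taxa$ids, ids)
  list(table = count_table(counts, "weed", taxa$codes), groups = groups)
}

#' Generate a synthetic archaeological assemblage
#'
#' Each sample is drawn from a mixture over the four group profiles, with an
#' optional off-manifold contamination component standing in for seeds from
#' a non-crop-processing pathway (for example dung-derived seeds). The
#' contamination composition is deliberately unlike any processing stage
#' (simultaneously heavy in `SHL` and `BFH`).
#'
#' @param profiles list of four group profiles.
#' @param stage_mixture numeric weights over groups 1-4, summing to 1; each
#'   sample's generating stage is drawn from these weights.
#' @param n number of samples (0 gives an empty table).
#' @param seed integer RNG seed (required).
#' @param contamination fraction in `[0, 1)` of each sample's expected
#'   composition replaced by the contamination component.
#' @param contamination_weights named composition over [ATTRIBUTE_CODES]
#'   for the contamination component; a default off-manifold profile is
#'   used when `NULL`.
#' @param overdispersed as in [generate_reference()].
#' @return list with `table` (a [count_table()]) and `stage` (the generating
#'   group per sample).
#' @export
generate_archaeological <- function(profiles = default_group_profiles(),
                                    stage_mixture = rep(0.25, 4), n = 30,
                                    seed, contamination = 0,
                                    contamination_weights = NULL,
                                    overdispersed = TRUE) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (abs(sum(stage_mixture) - 1) > 1e-8)
    stop("stage_mixture must sum to 1", call. = FALSE)
  set.seed(seed)
  taxa <- synthetic_taxa(profiles[[1L]]$taxa_per_code)
  if (is.null(contamination_weights)) {
    contamination_weights <- c(BHH = 0.02, BFH = 0.38, SHH = 0.02,
                               SHL = 0.38, SFH = 0.02, SFL = 0.18)
  }
  if (n == 0L) {
    counts <- matrix(0, length(taxa$ids), 0L,
                     dimnames = list(taxa$ids, character()))
    return(list(table = count_table(counts, "weed", taxa$codes),
                stage = integer()))
  }
  stage <- sample.int(4L, n, replace = TRUE, prob = stage_mixture)
  counts <- vapply(seq_len(n), function(i) {
    draw_sample(profiles[[stage[i]]], taxa, overdispersed,
                contamination = contamination,
                contamination_weights = contamination_weights)
  }, numeric(length(taxa$ids)))
  dimnames(counts) <- list(taxa$ids, sprintf("arch_s%03d", seq_len(n)))
  list(table = count_table(counts, "weed", taxa$codes), stage = stage)
}

#' Generate a ready-to-use synthetic reference set
#'
#' Convenience wrapper: generates reference counts, applies the attribute
#' transform and bundles the result as a [reference_set()].
#'
#' @inheritParams generate_reference
#' @return A [reference_set()].
#' @export
synthetic_reference_set <- function(profiles = default_group_profiles(),
                                    n_per_group = 25, seed,
                                    overdispersed = TRUE) {
  ref <- generate_reference(profiles, n_per_group, seed,
                            overdispersed = overdispersed)
  am <- attribute_transform(ref$table)
  reference_set(am, ref$groups,
                provenance = sprintf("synthetic (seed %d)", seed))
}

#' Loader for a user-supplied ethnographic reference CSV
#'
#' Users who hold the published ethnographic attribute data can load it
#' here: a CSV with a `sample` column, a `group` column (1-4) and the six
#' attribute-score columns. The result slots in wherever the synthetic
#' reference is used.
#'
#' @param path CSV path.
#' @return A [reference_set()].
#' @export
read_reference_set <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(colnames(df))
  colnames(df) <- ifelse(nm %in% c("sample", "group"), nm, colnames(df))
  if (!all(c("sample", "group") %in% colnames(df)))
    stop("expected 'sample' and 'group' columns in ", path, call. = FALSE)
  m <- as.matrix(df[ATTRIBUTE_CODES])
  rownames(m) <- as.character(df$sample)
  reference_set(attribute_matrix(m), df$group,
                provenance = paste("file:", path))
}

#' Synthetic ethnographic grain/rachis/weeds proportions
#'
#' Generates a synthetic stand-in for the ethnographic triplot reference:
#' per group, per-sample grain/rachis/weed totals are drawn from a Dirichlet
#' around a stage-typical composition (fine sieve product grain-rich;
#' winnowing and coarse sieve by-products rachis/weed-rich; fine sieve
#' by-product weed-dominated) times a Poisson item total.
#'
#' @param n_per_group samples per group.
#' @param seed integer RNG seed (required).
#' @param items_per_sample expected items per sample.
#' @return list with `table` (a [triplot_table()]) and `groups` (integer
#'   label per sample).
#' @export
synthetic_triplot_reference <- function(n_per_group = 10, seed,
                                        items_per_sample = 200) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  base <- list(
    `1` = c(grain = 0.08, rachis = 0.32, weeds = 0.60),
    `2` = c(grain = 0.10, rachis = 0.55, weeds = 0.35),
    `3` = c(grain = 0.07, rachis = 0.08, weeds = 0.85),
    `4` = c(grain = 0.90, rachis = 0.03, weeds = 0.07)
  )
  rows <- list()
  groups <- integer()
  for (g in 1:4) {
    for (i in seq_len(n_per_group)) {
      p <- rdirichlet1(base[[g]] * 40)
      n <- max(1L, stats::rpois(1L, items_per_sample))
      cnt <- stats::rmultinom(1L, n, p)[, 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("eth_g%d_t%02d", g, i),
        grain = cnt[1L], rachis = cnt[2L], weeds = cnt[3L],
        stringsAsFactors = FALSE)
      groups <- c(groups, g)
    }
  }
  list(table = triplot_table(do.call(rbind, rows)), groups = groups)
}
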