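## Seeded synthetic generators emulating every pipeline input: activity
## libraries with a planted enriched scaffold, descriptor datasets with
## planted informative columns, pharmacophore fingerprint strings with
## class-shifted token frequencies, and docking outputs (energies +
## interaction reports) with a planted active/inactive separation.

#' Synthetic study specification
#'
#' Bundles the knobs of all synthetic generators. The same seed always
#' produces byte-identical output.
#'
#' @param seed integer RNG seed.
#' @param n_compounds number of compounds in a generated activity library.
#' @param scaffold_effect pIC50 mean shift added to the planted (quinazoline)
#'   scaffold family.
#' @param censored_fraction fraction of records whose potency is replaced by
#'   a censored qualifier.
#' @param n_patterns fingerprint vocabulary size.
#' @param pattern_class_effect log-scale shift of informative pattern
#'   frequency in actives.
#' @param energy_gap mean active-inactive binding-energy separation in
#'   kcal/mol (positive = actives bind more strongly, i.e. more negative).
#' @param energy_sd binding-energy standard deviation (kcal/mol).
#' @param planted_interactions data.frame with columns \code{residue},
#'   \code{type}: interactions over-represented in actives.
#' @return An object of class \code{"SyntheticSpec"} (a validated list).
#' @export
#' @examples
#' sp <- syntheticSpec(seed = 1, n_compounds = 60)
#' lib <- genActivityLibrary(sp)
syntheticSpec <- function(seed = 1L, n_compounds = 192L, scaffold_effect = 1.5,
                          censored_fraction = 0.3, n_patterns = 60L,
                          pattern_class_effect = 1.0, energy_gap = 1.5,
                          energy_sd = 1.0,
                          planted_interactions = data.frame(
                            residue = c("Lys85", "Tyr156", "Glu161", "Lys164",
                                        "Tyr156", "Glu161"),
                            type = c("hydrophobic", "hydrophobic", "hydrophobic",
                                     "hydrophobic", "hbond", "hbond"),
                            stringsAsFactors = FALSE)) {
  spec <- list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
               scaffold_effect = scaffold_effect,
               censored_fraction = censored_fraction,
               n_patterns = as.integer(n_patterns),
               pattern_class_effect = pattern_class_effect,
               energy_gap = energy_gap, energy_sd = energy_sd,
               planted_interactions = planted_interactions)
  if (spec$n_compounds < 2L) stop("n_compounds must be >= 2")
  if (spec$censored_fraction < 0 || spec$censored_fraction > 1) {
    stop("censored_fraction must lie in [0, 1]")
  }
  if (spec$energy_sd <= 0) stop("energy_sd must be positive")
  class(spec) <- "SyntheticSpec"
  spec
}

#' Generate a synthetic activity library with a planted enriched scaffold
#'
#' Draws compounds from the embedded drug-like SMILES fixtures; each
#' compound inherits its fixture's scaffold family and a pIC50 from
#' Normal(5.8, 0.8), shifted upward by \code{scaffold_effect} for the
#' planted quinazoline family. IC50 values are computed by inverting the
#' pIC50; a \code{censored_fraction} of records lose their potency and
#' become censored.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param base_pic50,pic50_sd base potency distribution (defaults 5.8, 0.8).
#' @return A \linkS4class{CompoundLibrary} whose records carry a
#'   \code{scaffold_family} ground-truth column; metadata names the planted
#'   scaffold family.
#' @export
genActivityLibrary <- function(spec, base_pic50 = 5.8, pic50_sd = 0.8) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  fx <- fixtureSmilesTable()
  withSeed(spec$seed, {
    pick <- sample(nrow(fx), spec$n_compounds, replace = TRUE)
    fam <- fx$family[pick]
    pic50 <- rnorm(spec$n_compounds, base_pic50, pic50_sd) +
      ifelse(fam == "quinazoline", spec$scaffold_effect, 0)
    censored <- runif(spec$n_compounds) < spec$censored_fraction
  })
  ic50 <- fromPIC50(pic50)
  rec <- data.frame(
    compound_id = sprintf("SYN%04d", seq_len(spec$n_compounds)),
    smiles = fx$smiles[pick],
    ic50_nM = ifelse(censored, NA_real_, ic50),
    qualifier = ifelse(censored, "censored", "exact"),
    pic50 = ifelse(censored, NA_real_, pic50),
    role = "inhibitor",
    scaffold_family = fam,
    stringsAsFactors = FALSE
  )
  CompoundLibrary(rec, name = "synthetic-activity",
                  metadata = list(planted_scaffold = "quinazoline", spec = spec))
}

#' Generate a descriptor regression dataset with planted informative columns
#'
#' Informative columns drive the response through fixed coefficients
#' (linear) or a smooth interaction form (nonlinear); noise columns are
#' independent of the response. Column names flag the ground truth
#' (\code{INF*} vs \code{NOISE*}).
#'
#' @param n observations; must exceed \code{p_informative}.
#' @param p_informative,p_noise numbers of informative and noise columns.
#' @param model \code{"linear"} or \code{"nonlinear"}.
#' @param noise_sd residual standard deviation of the response.
#' @param seed RNG seed.
#' @return list with \code{X} (numeric matrix), \code{y} (response vector)
#'   and \code{informative} (names of the planted columns).
#' @export
genDescriptorDataset <- function(n, p_informative, p_noise,
                                 model = c("linear", "nonlinear"),
                                 noise_sd = 1, seed = 1L) {
  model <- match.arg(model)
  stopifnot(n > p_informative, p_informative >= 1, p_noise >= 0)
  p <- p_informative + p_noise
  withSeed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    eps <- rnorm(n, 0, noise_sd)
  })
  colnames(X) <- c(sprintf("INF%02d", seq_len(p_informative)),
                   if (p_noise > 0) sprintf("NOISE%02d", seq_len(p_noise)))
  Xi <- X[, seq_len(p_informative), drop = FALSE]
  if (model == "linear") {
    beta <- 2 * 0.85^(seq_len(p_informative) - 1) *
      rep_len(c(1, -1), p_informative)
    y <- drop(Xi %*% beta) + eps
  } else {
    g <- function(j) Xi[, ((j - 1) %% p_informative) + 1]
    y <- 1.5 * sin(pi * g(1)) + g(2)^2 +
      if (p_informative >= 3) 2 * g(1) * g(3) else 0
    if (p_informative >= 4) y <- y + g(4)
    if (p_informative >= 5) y <- y - 1.2 * g(5)
    y <- y + eps
  }
  list(X = X, y = y, informative = colnames(X)[seq_len(p_informative)])
}

#' Generate pharmacophore fingerprint strings with class-shifted patterns
#'
#' Emulates exported fingerprint strings: one line per compound, a compound
#' id, a tab, and delimiter-separated pattern tokens. Token counts follow
#' Poisson distributions whose rates, for a designated informative subset of
#' patterns, are multiplied by \code{exp(+/- pattern_class_effect)} in the
#' active class.
#'
#' @param n number of compounds.
#' @param spec a \code{\link{syntheticSpec}} (uses \code{n_patterns},
#'   \code{pattern_class_effect}, \code{seed}).
#' @param delimiter token delimiter within a line (default ";").
#' @param labels optional 0/1 class vector of length \code{n}; drawn
#'   Bernoulli(0.5) when NULL. Supplying labels ties the fingerprints to an
#'   existing library's activity classes.
#' @param ids optional compound ids (defaults to SYN0001, ...).
#' @return list with \code{lines} (character vector), \code{labels}
#'   (integer 0/1), and \code{informative} (the shifted pattern tokens).
#' @export
genFlexophoreStrings <- function(n, spec, delimiter = ";", labels = NULL,
                                 ids = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (spec$n_patterns < 5L) stop("n_patterns must be >= 5")
  if (n == 0L) {
    return(list(lines = character(0), labels = integer(0),
                informative = character(0)))
  }
  vocab <- sprintf("FLX%03d", seq_len(spec$n_patterns))
  if (is.null(ids)) ids <- sprintf("SYN%04d", seq_len(n))
  stopifnot(length(ids) == n)
  n_inf <- min(8L, spec$n_patterns)
  sign_j <- rep_len(c(1, -1), n_inf)
  fixed_labels <- labels
  withSeed(spec$seed, {
    base <- runif(spec$n_patterns, 0.4, 1.6)
    labels <- if (is.null(fixed_labels)) rbinom(n, 1L, 0.5) else as.integer(fixed_labels)
    counts <- matrix(0L, n, spec$n_patterns)
    for (j in seq_len(spec$n_patterns)) {
      lam <- rep(base[j], n)
      if (j <= n_inf) {
        lam <- lam * exp(sign_j[j] * spec$pattern_class_effect * labels)
      }
      counts[, j] <- rpois(n, lam)
    }
  })
  lines <- vapply(seq_len(n), function(i) {
    toks <- rep(vocab, counts[i, ])
    paste0(ids[i], "\t", paste(toks, collapse = delimiter))
  }, character(1))
  list(lines = lines, labels = labels, informative = vocab[seq_len(n_inf)])
}

#' Generate synthetic docking outputs with planted signal
#'
#' Active binding energies are drawn from Normal(mu_active, sd) and
#' inactive from Normal(mu_active + energy_gap, sd), so a positive gap means
#' actives bind more strongly (more negative energies). The planted
#' interactions occur in actives with higher probability; a set of
#' background interactions occurs at equal rates in both classes. The
#' reference fingerprint carries all planted interactions.
#'
#' @param n_active,n_inactive class sizes (each >= 1).
#' @param spec a \code{\link{syntheticSpec}}.
#' @param method docking method label written to the energies table.
#' @param mu_active mean active binding energy (kcal/mol, default -10).
#' @param p_active,p_inactive occurrence probability of planted interactions
#'   in actives and inactives.
#' @return list with \code{energies} (data.frame ligand_id, method,
#'   binding_energy), \code{interactions} (data.frame ligand_id, residue,
#'   type), \code{labels} (named 0/1 vector), and \code{reference}
#'   (data.frame residue, type).
#' @export
genDockingResults <- function(n_active, n_inactive, spec, method = "AD4",
                              mu_active = -10, p_active = 0.85,
                              p_inactive = 0.25) {
  stopifnot(inherits(spec, "SyntheticSpec"), n_active >= 1, n_inactive >= 1)
  ids <- c(sprintf("ACT%04d", seq_len(n_active)),
           sprintf("DEC%04d", seq_len(n_inactive)))
  labels <- setNames(c(rep(1L, n_active), rep(0L, n_inactive)), ids)
  planted <- spec$planted_interactions
  background <- data.frame(
    residue = c("Ala104", "Leu83", "Phe88", "Gly160", "Val107", "Arg159"),
    type = c("hydrophobic", "hydrophobic", "pi_stack", "hbond",
             "hydrophobic", "salt_bridge"),
    stringsAsFactors = FALSE
  )
  withSeed(spec$seed, {
    energy <- c(rnorm(n_active, mu_active, spec$energy_sd),
                rnorm(n_inactive, mu_active + spec$energy_gap, spec$energy_sd))
    rows <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      p_pl <- if (labels[i] == 1L) p_active else p_inactive
      hit_pl <- runif(nrow(planted)) < p_pl
      hit_bg <- runif(nrow(background)) < 0.3
      rows[[i]] <- rbind(
        if (any(hit_pl)) cbind(ligand_id = ids[i], planted[hit_pl, , drop = FALSE]),
        if (any(hit_bg)) cbind(ligand_id = ids[i], background[hit_bg, , drop = FALSE])
      )
    }
  })
  interactions <- do.call(rbind, rows)
  if (is.null(interactions)) {
    interactions <- data.frame(ligand_id = character(), residue = character(),
                               type = character(), stringsAsFactors = FALSE)
  }
  rownames(interactions) <- NULL
  list(
    energies = data.frame(ligand_id = ids, method = method,
                          binding_energy = energy, stringsAsFactors = FALSE),
    interactions = interactions,
    labels = labels,
    reference = planted
  )
}
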