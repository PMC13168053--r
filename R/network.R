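# Reaction-network reconstruction for the MEK-isoform ERK cascade.
#
# Species are generated programmatically by applying the rule set to a seed
# set until no new species appear (fixpoint), never hand-enumerated.  A MEK
# protomer carries an activation-site state (a = 0/1), and for MEK1 also a
# T292 state (t = 0/1) and PHP occupancy (php = 0/1, only when t = 1).
# Dimers are canonicalized by sorting protomer labels, so A::B == B::A.

pool_species <- function(name) list(type = "pool", name = name, label = name)

mek_protomer <- function(iso, a, t = 0L, php = 0L) {
  list(iso = iso, a = as.integer(a), t = as.integer(t), php = as.integer(php))
}

protomer_label <- function(pr) {
  if (pr$iso == "MEK1") {
    sprintf("MEK1(a%d,t%d%s)", pr$a, pr$t, if (pr$php == 1L) ",PHP" else "")
  } else {
    sprintf("MEK2(a%d)", pr$a)
  }
}

mek_species <- function(protomers) {
  labs <- vapply(protomers, protomer_label, character(1))
  o <- order(labs)
  list(type = "mek", protomers = protomers[o],
       label = paste(labs[o], collapse = "::"))
}

# Replace one field of one protomer, re-canonicalizing the species.
mod_protomer <- function(sp, k, field, value) {
  prs <- sp$protomers
  prs[[k]][[field]] <- as.integer(value)
  mek_species(prs)
}

rxn <- function(rate, reactants, products) {
  list(rate = rate, reactants = reactants, products = products)
}

# All reactions fireable from the current species set.  `specs` is a named
# list (label -> species structure); `active` maps a rate-constant name to
# TRUE unless the variant structurally zeroes it.
gen_reactions <- function(specs, active) {
  out <- list()
  add <- function(r) out[[length(out) + 1L]] <<- r
  has <- function(lab) !is.null(specs[[lab]])
  P <- function(name) pool_species(name)

  pool_rule <- function(rate, reactants, products) {
    if (active(rate) && all(vapply(reactants, `[[`, "", "label") %in% names(specs)))
      add(rxn(rate, reactants, products))
  }

  # receptor module
  pool_rule("c1L", list(P("EGFR")), list(P("EGFR_L")))
  pool_rule("c2",  list(P("EGFR_L"), P("EGFR_L")), list(P("EGFR_D")))
  pool_rule("t1",  list(P("EGFR_D")), list(P("EGFR_Dp")))
  pool_rule("d3",  list(P("EGFR_D")), list())
  pool_rule("d3",  list(P("EGFR_Dp")), list())
  pool_rule("d3",  list(P("EGFR_Dp_SOS1")), list(P("SOS1")))
  pool_rule("b1",  list(P("EGFR_Dp"), P("SOS1")), list(P("EGFR_Dp_SOS1")))
  pool_rule("n1",  list(P("EGFR_Dp_SOS1")), list(P("EGFR_Dp"), P("SOS1")))
  # RAS/RAF
  pool_rule("a1",  list(P("EGFR_Dp_SOS1"), P("RAS_GDP")),
                   list(P("EGFR_Dp_SOS1"), P("RAS_GTP")))
  pool_rule("i1",  list(P("RAS_GTP")), list(P("RAS_GDP")))
  pool_rule("a2",  list(P("RAF"), P("RAS_GTP")), list(P("RAF_a"), P("RAS_GTP")))
  pool_rule("i2",  list(P("RAF_a")), list(P("RAF")))
  # ERK dephosphorylation and SOS1 feedback
  pool_rule("u2",  list(P("ERK_pp")), list(P("ERK")))
  pool_rule("p3",  list(P("ERK_pp"), P("SOS1")), list(P("ERK_pp"), P("SOS1_p")))
  pool_rule("u3",  list(P("SOS1_p")), list(P("SOS1")))

  meks <- Filter(function(s) s$type == "mek", specs)

  for (sp in meks) {
    prs <- sp$protomers
    n_php <- sum(vapply(prs, `[[`, 0L, "php"))
    for (k in seq_along(prs)) {
      pr <- prs[[k]]
      # activation-site phosphorylation by active RAF and constitutive removal
      if (pr$a == 0L && has("RAF_a") && active("p1"))
        add(rxn("p1", list(P("RAF_a"), sp), list(P("RAF_a"), mod_protomer(sp, k, "a", 1))))
      if (pr$a == 1L && active("u1"))
        add(rxn("u1", list(sp), list(mod_protomer(sp, k, "a", 0))))
      # ERK phosphorylation by activation-phosphorylated protomers
      if (pr$a == 1L && has("ERK")) {
        rate <- if (pr$iso == "MEK1") "p2a" else "p2b"
        if (active(rate)) add(rxn(rate, list(sp, P("ERK")), list(sp, P("ERK_pp"))))
      }
      if (pr$iso == "MEK1") {
        # T292 feedback phosphorylation by doubly phosphorylated ERK
        if (pr$t == 0L && has("ERK_pp") && active("p4"))
          add(rxn("p4", list(P("ERK_pp"), sp), list(P("ERK_pp"), mod_protomer(sp, k, "t", 1))))
        if (pr$t == 1L && pr$php == 0L && active("u4"))
          add(rxn("u4", list(sp), list(mod_protomer(sp, k, "t", 0))))
        # PHP phosphatase binding to the T292 mark
        if (pr$t == 1L && pr$php == 0L && has("PHP") && active("b5"))
          add(rxn("b5", list(P("PHP"), sp), list(mod_protomer(sp, k, "php", 1))))
        if (pr$php == 1L && active("n5"))
          add(rxn("n5", list(sp), list(P("PHP"), mod_protomer(sp, k, "php", 0))))
      }
      # PHP-driven dephosphorylation of activation sites in the same complex:
      # one event per (PHP-bound protomer, phosphorylated site) pair.
      if (pr$a == 1L && n_php > 0L && active("u5")) {
        for (dummy in seq_len(n_php))
          add(rxn("u5", list(sp), list(mod_protomer(sp, k, "a", 0))))
      }
    }
  }

  # MEK dimerization among monomers, state-preserving
  monos <- Filter(function(s) length(s$protomers) == 1L, meks)
  dim_rate <- function(i1, i2) {
    if (i1 == "MEK1" && i2 == "MEK1") c("b2", "n2")
    else if (i1 == "MEK2" && i2 == "MEK2") c("b3", "n3")
    else c("b4", "n4")
  }
  if (length(monos) >= 1L) {
    for (i in seq_along(monos)) for (j in i:length(monos)) {
      mi <- monos[[i]]; mj <- monos[[j]]
      rt <- dim_rate(mi$protomers[[1]]$iso, mj$protomers[[1]]$iso)
      if (active(rt[1]))
        add(rxn(rt[1], list(mi, mj), list(mek_species(c(mi$protomers, mj$protomers)))))
    }
  }
  # dissociation generated from every reachable dimer
  dimers <- Filter(function(s) length(s$protomers) == 2L, meks)
  for (d in dimers) {
    rt <- dim_rate(d$protomers[[1]]$iso, d$protomers[[2]]$iso)
    if (active(rt[2]))
      add(rxn(rt[2], list(d),
              list(mek_species(d$protomers[1]), mek_species(d$protomers[2]))))
  }
  out
}

# moiety content of one species (columns of the conservation matrix)
moiety_counts <- function(sp) {
  m <- c(EGFR = 0, SOS1 = 0, RAS = 0, RAF = 0, ERK = 0, PHP = 0,
         MEK1 = 0, MEK2 = 0)
  if (sp$type == "pool") {
    switch(sp$name,
      EGFR = , EGFR_L = { m["EGFR"] <- 1 },
      EGFR_D = , EGFR_Dp = { m["EGFR"] <- 2 },
      EGFR_Dp_SOS1 = { m["EGFR"] <- 2; m["SOS1"] <- 1 },
      SOS1 = , SOS1_p = { m["SOS1"] <- 1 },
      RAS_GDP = , RAS_GTP = { m["RAS"] <- 1 },
      RAF = , RAF_a = { m["RAF"] <- 1 },
      ERK = , ERK_pp = { m["ERK"] <- 1 },
      PHP = { m["PHP"] <- 1 })
  } else {
    for (pr in sp$protomers) {
      m[pr$iso] <- m[pr$iso] + 1
      if (pr$php == 1L) m["PHP"] <- m["PHP"] + 1
    }
  }
  m
}

# observable weights of one species
observable_weights <- function(sp) {
  w <- c(MEK_pRDS = 0, pERK1_2_wt = 0, pEGFR = 0, pSOS1 = 0)
  if (sp$type == "pool") {
    if (sp$name == "ERK_pp") w["pERK1_2_wt"] <- 1
    if (sp$name %in% c("EGFR_Dp", "EGFR_Dp_SOS1")) w["pEGFR"] <- 2
    if (sp$name == "SOS1_p") w["pSOS1"] <- 1
  } else {
    w["MEK_pRDS"] <- sum(vapply(sp$protomers, `[[`, 0L, "a"))
  }
  w
}

variant_zero_rates <- function(variant) {
  switch(variant, WT = character(0), KO = character(0),
         N78G = c("b2", "b4"), T292A = "p4", T292D = "u4")
}

seed_species <- function(variant) {
  seeds <- list(pool_species("EGFR"), pool_species("SOS1"),
                pool_species("RAS_GDP"), pool_species("RAF"),
                pool_species("ERK"), pool_species("PHP"),
                mek_species(list(mek_protomer("MEK2", 0))))
  if (variant != "KO") {
    t0 <- if (variant == "T292D") 1L else 0L
    seeds <- c(seeds, list(mek_species(list(mek_protomer("MEK1", 0, t0)))))
  }
  seeds
}

#' Build the reaction network of a cell-line variant
#'
#' Expands the mass-action rule set to fixpoint from the variant's seed
#' species.  Variants prune structurally: the knockout seeds no MEK1, N78G
#' omits MEK1 homo-/heterodimerization, T292A omits the T292 feedback
#' phosphorylation, and T292D starts all MEK1 T292-phosphorylated with an
#' irreversible mark.
#'
#' @param variant One of [variant_ids()].
#' @return A `cascade_network`: species inventory, aggregated mass-action
#'   reactions (rate-constant name, multiplicity, reactant/product indices),
#'   stoichiometry, moiety matrix, and observable weight matrix.
#' @export
build_network <- function(variant) {
  variant <- match.arg(variant, variant_ids())
  cached <- .network_cache[[variant]]
  if (!is.null(cached)) return(cached)

  zero <- variant_zero_rates(variant)
  active <- function(rate) !(rate %in% zero)

  specs <- list()
  for (s in seed_species(variant)) specs[[s$label]] <- s
  repeat {
    rxns <- gen_reactions(specs, active)
    added <- FALSE
    for (r in rxns) for (p in r$products) {
      if (is.null(specs[[p$label]])) { specs[[p$label]] <- p; added <- TRUE }
    }
    if (!added) break
  }

  # aggregate per-site reactions into multiplicity-weighted reactions
  keys <- vapply(rxns, function(r) {
    paste(r$rate,
          paste(sort(vapply(r$reactants, `[[`, "", "label")), collapse = "+"),
          paste(sort(vapply(r$products, `[[`, "", "label")), collapse = "+"),
          sep = " | ")
  }, character(1))
  agg <- split(seq_along(rxns), keys)

  species <- names(specs)
  idx <- stats::setNames(seq_along(species), species)

  reactions <- lapply(agg, function(ii) {
    r <- rxns[[ii[1]]]
    rl <- vapply(r$reactants, `[[`, "", "label")
    pl <- vapply(r$products, `[[`, "", "label")
    net <- table(factor(pl, levels = species)) - table(factor(rl, levels = species))
    nz <- which(net != 0)
    list(rate = r$rate, mult = length(ii),
         r1 = idx[[rl[1]]], r2 = if (length(rl) == 2L) idx[[rl[2]]] else NA_integer_,
         reactants = rl, products = pl,
         s_idx = as.integer(nz), s_val = as.numeric(net[nz]))
  })
  names(reactions) <- NULL

  moieties <- t(vapply(specs, moiety_counts, numeric(8)))
  obs_w <- t(vapply(specs, observable_weights, numeric(4)))

  net <- structure(list(
    variant = variant, species = species, spec_struct = specs,
    reactions = reactions,
    n_species = length(species), n_reactions = length(reactions),
    moieties = moieties, obs_weights = obs_w,
    compiled = compile_network_arrays(reactions, length(species))
  ), class = "cascade_network")
  assign(variant, net, envir = .network_cache)
  net
}

# flatten reactions into the integer/double arrays the C right-hand side uses
compile_network_arrays <- function(reactions, n_species) {
  nr <- length(reactions)
  re1 <- vapply(reactions, function(r) r$r1, 1L) - 1L
  re2 <- vapply(reactions, function(r) if (is.na(r$r2)) 0L else r$r2, 1L) - 1L
  s_len <- vapply(reactions, function(r) length(r$s_idx), 1L)
  sptr <- c(0L, cumsum(s_len))
  sidx <- unlist(lapply(reactions, `[[`, "s_idx"), use.names = FALSE) - 1L
  sval <- unlist(lapply(reactions, `[[`, "s_val"), use.names = FALSE)
  rate <- vapply(reactions, `[[`, "", "rate")
  list(re1 = as.integer(re1), re2 = as.integer(re2),
       sptr = as.integer(sptr), sidx = as.integer(sidx), sval = as.numeric(sval),
       rate = rate, rate_idx = match(rate, names(default_params())),
       mult = vapply(reactions, function(r) as.numeric(r$mult), 1.0),
       n_species = as.integer(n_species), n_reactions = as.integer(nr))
}

.network_cache <- new.env(parent = emptyenv())

#' @export
print.cascade_network <- function(x, ...) {
  cat(sprintf("cascade_network [%s]: %d species, %d reactions\n",
              x$variant, x$n_species, x$n_reactions))
  invisible(x)
}

#' Initial copy-number state of a network
#'
#' @param network A `cascade_network`.
#' @param params Parameter vector; the network's variant transformation is
#'   applied first, so passing the base (WT) set is always safe.
#' @return Named numeric vector over the network's species.
#' @export
initial_state <- function(network, params) {
  p <- apply_variant(params, network$variant)
  y <- stats::setNames(numeric(network$n_species), network$species)
  set1 <- function(lab, val) {
    if (lab %in% names(y)) y[lab] <<- val
    else if (val > 0) stop("nonzero initial value for absent species ", lab)
  }
  set1("EGFR", p[["EGFR0"]]); set1("SOS1", p[["SOS10"]])
  set1("RAS_GDP", p[["RAS0"]]); set1("RAF", p[["RAF0"]])
  set1("ERK", p[["ERK0"]]); set1("PHP", p[["PHP_MEK0"]])
  set1("MEK2(a0)", p[["MEK20"]])
  if (network$variant != "KO") {
    set1(protomer_label(mek_protomer("MEK1", 0, 0)),
         p[["MEK10"]] - p[["MEK1_T292p0"]])
    set1(protomer_label(mek_protomer("MEK1", 0, 1)), p[["MEK1_T292p0"]])
  }
  y
}

#' Export a network as auditable plain text
#'
#' Writes a one-reaction-per-line listing (`reactants -> products  rate x mult`)
#' and a species inventory CSV with moiety content.
#'
#' @param network A `cascade_network`.
#' @param reactions_file,species_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_network_files <- function(network, reactions_file, species_file) {
  lines <- vapply(network$reactions, function(r) {
    sprintf("%s -> %s  @ %s x%d",
            paste(r$reactants, collapse = " + "),
            if (length(r$products)) paste(r$products, collapse = " + ") else "0",
            r$rate, r$mult)
  }, character(1))
  writeLines(lines, reactions_file)
  inv <- data.frame(species = network$species, network$moieties,
                    check.names = FALSE)
  utils::write.csv(inv, species_file, row.names = FALSE)
  invisible(c(reactions_file, species_file))
}
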