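#' Atom-transition metabolic networks
#'
#' A `flux_network` holds reactions with carbon (atom-transition) maps, a
#' metabolite table with carbon counts and compartments, and the balanced /
#' external metabolite partition used for steady-state analysis. Networks are
#' written one reaction per line in a tab-separated dialect:
#'
#' ```
#' reaction_id <TAB> reversible {0,1} <TAB> kind <TAB> equation
#' ```
#'
#' where the equation spells each term as `metabolite (atommap)`, e.g.
#' `pyr.m (abc) -> accoa.m (bc) + co2.x (a)`. Carbon maps use lowercase
#' letters; every letter on the substrate side must appear exactly once on the
#' product side (carbon conservation), so CO2 release/uptake is always written
#' explicitly as a `co2.x` term. Reaction kinds are `enzymatic`, `transport`,
#' `mixing`, `dilution` and `exchange` (exchange with the medium). `mixing`
#' reactions carry no atom maps: they declare that the measured pool of a
#' dually compartmented metabolite is a blend of its cytosolic and
#' mitochondrial pools (`pyr.c + pyr.m -> pyr.meas`), weighted by a fitted
#' mixing fraction.
#'
#' Compartments are inferred from the metabolite id suffix: `.c` cytosol,
#' `.m` mitochondrion, `.x` extracellular, `.meas` measurement (virtual pool
#' seen by GC-MS after extraction homogenizes the compartments). Extracellular
#' and measurement species are external (exempt from balancing); cytosolic and
#' mitochondrial species are balanced.
#'
#' Lines starting with `#` are comments. A directive line
#' `@symmetric <TAB> id1 id2 ...` marks rotationally symmetric metabolites
#' (succinate, fumarate): every reaction producing them is simulated as two
#' half-flux variants with the forward and reversed atom map.
#'
#' @param text Character scalar (or vector of lines) with network file content.
#' @return A `flux_network` object: list with `reactions` (list of parsed
#'   reactions), `metabolites` (tibble: `metabolite`, `carbons`,
#'   `compartment`), `balanced`, `external` and `symmetric` (character
#'   vectors of metabolite ids).
#' @examples
#' net <- parse_network(c(
#'   "v1\t0\tenzymatic\tA.x (ab) -> B.c (ab)",
#'   "v2\t0\tenzymatic\tB.c (ab) -> C.x (ba)"
#' ))
#' tidy(net)
#' @export
parse_network <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  symmetric <- character()
  reactions <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    if (startsWith(ln, "@symmetric")) {
      symmetric <- c(symmetric, strsplit(trimws(sub("^@symmetric", "", ln)), "[ \t]+")[[1]])
      next
    }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 4) {
      abort(sprintf("network parse error at line %d: expected 4 tab-separated fields, got %d",
                    i, length(fields)))
    }
    rev_flag <- fields[[2]]
    if (!rev_flag %in% c("0", "1")) {
      abort(sprintf("network parse error at line %d: reversible flag must be 0 or 1", i))
    }
    kind <- fields[[3]]
    kinds <- c("enzymatic", "transport", "mixing", "dilution", "exchange")
    if (!kind %in% kinds) {
      abort(sprintf("network parse error at line %d: unknown kind '%s'", i, kind))
    }
    eq <- parse_equation(fields[[4]], with_maps = kind != "mixing", line = i)
    reactions[[length(reactions) + 1L]] <- list(
      id = fields[[1]], reversible = rev_flag == "1", kind = kind,
      substrates = eq$substrates, products = eq$products
    )
  }
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate reaction id: %s", ids[duplicated(ids)][1]))
  }
  net <- build_network(reactions, symmetric)
  validate_network(net)
  net
}

# split "a.c (abc) + b.m (de) -> c.m (abcde)" into substrate/product term lists
parse_equation <- function(eq, with_maps, line) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) {
    abort(sprintf("network parse error at line %d: equation must contain one '->'", line))
  }
  parse_side <- function(s) {
    terms <- strsplit(s, "+", fixed = TRUE)[[1]]
    lapply(terms, function(tm) {
      tm <- trimws(tm)
      if (with_maps) {
        m <- regmatches(tm, regexec("^([A-Za-z0-9_.]+)[ ]*\\(([a-z]+)\\)$", tm))[[1]]
        if (length(m) != 3) {
          abort(sprintf("network parse error at line %d: malformed term '%s'", line, tm))
        }
        list(metabolite = m[[2]], map = strsplit(m[[3]], "")[[1]])
      } else {
        if (!grepl("^[A-Za-z0-9_.]+$", tm)) {
          abort(sprintf("network parse error at line %d: malformed mixing term '%s'", line, tm))
        }
        list(metabolite = tm, map = character())
      }
    })
  }
  list(substrates = parse_side(sides[[1]]), products = parse_side(sides[[2]]))
}

metabolite_compartment <- function(id) {
  ifelse(grepl("\\.meas$", id), "measurement",
    ifelse(grepl("\\.x$", id), "extracellular",
      ifelse(grepl("\\.m$", id), "mitochondrion",
        ifelse(grepl("\\.c$", id), "cytosol", NA_character_))))
}

build_network <- function(reactions, symmetric = character()) {
  met_ids <- character()
  carbons <- integer()
  for (r in reactions) {
    for (tm in c(r$substrates, r$products)) {
      nc <- length(tm$map)
      j <- match(tm$metabolite, met_ids)
      if (is.na(j)) {
        met_ids <- c(met_ids, tm$metabolite)
        carbons <- c(carbons, nc)
      } else if (r$kind != "mixing" && carbons[[j]] == 0L) {
        carbons[[j]] <- nc
      } else if (r$kind != "mixing" && nc != carbons[[j]]) {
        abort(sprintf(
          "validation error in reaction '%s': carbon map of '%s' has length %d, declared %d",
          r$id, tm$metabolite, nc, carbons[[j]]))
      }
    }
  }
  comp <- metabolite_compartment(met_ids)
  if (anyNA(comp)) {
    abort(sprintf("undeclared compartment for metabolite '%s' (use .c/.m/.x/.meas suffix)",
                  met_ids[is.na(comp)][1]))
  }
  mets <- tibble::tibble(metabolite = met_ids, carbons = carbons, compartment = comp)
  balanced <- met_ids[comp %in% c("cytosol", "mitochondrion")]
  external <- met_ids[comp %in% c("extracellular", "measurement")]
  structure(
    list(reactions = reactions, metabolites = mets,
         balanced = balanced, external = external,
         symmetric = intersect(symmetric, met_ids)),
    class = "flux_network"
  )
}

validate_network <- function(net) {
  for (r in net$reactions) {
    if (r$kind == "mixing") {
      if (length(r$substrates) != 2L || length(r$products) != 1L) {
        abort(sprintf("validation error in mixing reaction '%s': must combine exactly two pools into one",
                      r$id))
      }
      base <- unique(sub("\\.[a-z]+$", "", vapply(c(r$substrates, r$products), `[[`, "", "metabolite")))
      if (length(base) != 1L) {
        abort(sprintf("validation error in mixing reaction '%s': pools must be the same chemical species",
                      r$id))
      }
      comps <- metabolite_compartment(vapply(r$substrates, `[[`, "", "metabolite"))
      if (!setequal(comps, c("cytosol", "mitochondrion"))) {
        abort(sprintf("validation error in mixing reaction '%s': pools must come from cytosol and mitochondrion",
                      r$id))
      }
      next
    }
    sub_letters <- sort(unlist(lapply(r$substrates, `[[`, "map")))
    prod_letters <- sort(unlist(lapply(r$products, `[[`, "map")))
    if (anyDuplicated(sub_letters) || anyDuplicated(prod_letters) ||
        !identical(sub_letters, prod_letters)) {
      abort(sprintf("validation error in reaction '%s': carbon maps are not balanced (substrates '%s', products '%s')",
                    r$id, paste(sub_letters, collapse = ""), paste(prod_letters, collapse = "")))
    }
  }
  # every balanced metabolite must have a producer and a consumer
  prod <- cons <- character()
  for (r in net$reactions) {
    if (r$kind == "mixing") next
    s <- vapply(r$substrates, `[[`, "", "metabolite")
    p <- vapply(r$products, `[[`, "", "metabolite")
    cons <- c(cons, s)
    prod <- c(prod, p)
    if (r$reversible) {
      cons <- c(cons, p)
      prod <- c(prod, s)
    }
  }
  missing_prod <- setdiff(net$balanced, prod)
  if (length(missing_prod)) {
    abort(sprintf("validation error: balanced metabolite '%s' has no producing reaction",
                  missing_prod[1]))
  }
  missing_cons <- setdiff(net$balanced, cons)
  if (length(missing_cons)) {
    abort(sprintf("validation error: balanced metabolite '%s' has no consuming reaction",
                  missing_cons[1]))
  }
  invisible(net)
}

#' Read a network file from disk
#'
#' @param path Path to a network TSV file (see [parse_network] for the dialect).
#' @return A `flux_network`.
#' @export
read_network <- function(path) {
  parse_network(readLines(path, warn = FALSE))
}

#' @export
print.flux_network <- function(x, ...) {
  n_mix <- sum(vapply(x$reactions, function(r) r$kind == "mixing", TRUE))
  cat(sprintf("<flux_network> %d reactions (%d mixing), %d metabolites (%d balanced)\n",
              length(x$reactions), n_mix, nrow(x$metabolites), length(x$balanced)))
  cat(sprintf("  degrees of freedom: %d\n", network_dof(x)))
  invisible(x)
}

#' @describeIn parse_network Reaction table of a network as a tibble.
#' @param x A `flux_network`.
#' @param ... Unused.
#' @export
tidy.flux_network <- function(x, ...) {
  tibble::tibble(
    reaction = vapply(x$reactions, `[[`, "", "id"),
    reversible = vapply(x$reactions, `[[`, TRUE, "reversible"),
    kind = vapply(x$reactions, `[[`, "", "kind"),
    equation = vapply(x$reactions, format_reaction, "")
  )
}

format_reaction <- function(r) {
  fmt <- function(tms) paste(vapply(tms, function(tm) {
    if (length(tm$map)) sprintf("%s (%s)", tm$metabolite, paste(tm$map, collapse = ""))
    else tm$metabolite
  }, ""), collapse = " + ")
  paste(fmt(r$substrates), "->", fmt(r$products))
}

# non-mixing reactions, in network order
core_reactions <- function(net) {
  Filter(function(r) r$kind != "mixing", net$reactions)
}

mixing_reactions <- function(net) {
  Filter(function(r) r$kind == "mixing", net$reactions)
}

#' Stoichiometric matrix restricted to balanced metabolites
#'
#' Rows are balanced metabolites, columns are non-mixing reactions (mixing
#' reactions are virtual measurement constructs and carry no material flux).
#'
#' @param net A `flux_network`.
#' @return Numeric matrix with dimnames.
#' @export
stoichiometry <- function(net) {
  rxns <- core_reactions(net)
  S <- matrix(0, nrow = length(net$balanced), ncol = length(rxns),
              dimnames = list(net$balanced, vapply(rxns, `[[`, "", "id")))
  for (j in seq_along(rxns)) {
    r <- rxns[[j]]
    for (tm in r$substrates) {
      i <- match(tm$metabolite, net$balanced)
      if (!is.na(i)) S[i, j] <- S[i, j] - 1
    }
    for (tm in r$products) {
      i <- match(tm$metabolite, net$balanced)
      if (!is.na(i)) S[i, j] <- S[i, j] + 1
    }
  }
  S
}

#' Degrees of freedom of the flux space
#'
#' Dimension of the null space of the balanced stoichiometric matrix:
#' the number of free fluxes needed to specify a steady-state flux map.
#'
#' @param net A `flux_network`.
#' @return Integer.
#' @export
network_dof <- function(net) {
  S <- stoichiometry(net)
  ncol(S) - qr(S)$rank
}

#' Free-flux parameterization of the steady-state flux space
#'
#' Partitions reactions into dependent (pivot) and free columns via QR with
#' column pivoting, so that any steady-state net-flux vector is determined by
#' the free fluxes: `v_dep = -S1^{-1} S2 v_free`.
#'
#' @param net A `flux_network`.
#' @return List with `free`, `dependent` (reaction ids), and `expand(v_free)`
#'   returning the full named net-flux vector.
#' @export
flux_basis <- function(net) {
  S <- stoichiometry(net)
  qrS <- qr(S)
  r <- qrS$rank
  piv <- qrS$pivot
  dep <- piv[seq_len(r)]
  free <- piv[-seq_len(r)]
  if (length(free) == 0L) {
    abort("network has no degrees of freedom: flux map fully determined (or empty)")
  }
  S1 <- S[, dep, drop = FALSE]
  S2 <- S[, free, drop = FALSE]
  # v_dep = -S1^+ S2 v_free (S1 has full column rank r; use QR solve)
  Tmat <- -qr.solve(qr(S1), S2)
  rxn_ids <- colnames(S)
  expand <- function(v_free) {
    stopifnot(length(v_free) == length(free))
    v <- numeric(ncol(S))
    v[free] <- v_free
    v[dep] <- as.vector(Tmat %*% v_free)
    names(v) <- rxn_ids
    v
  }
  list(free = rxn_ids[free], dependent = rxn_ids[dep], expand = expand,
       transform = Tmat, n_reactions = ncol(S))
}

#' Steady-state balance residuals of a net-flux vector
#'
#' @param net A `flux_network`.
#' @param net_flux Named numeric vector of net fluxes for all non-mixing
#'   reactions (names are reaction ids).
#' @return Named numeric vector of production-minus-consumption per balanced
#'   metabolite.
#' @export
balance_residuals <- function(net, net_flux) {
  S <- stoichiometry(net)
  v <- net_flux[colnames(S)]
  if (anyNA(v)) {
    abort(sprintf("net_flux is missing reactions: %s",
                  paste(setdiff(colnames(S), names(net_flux)), collapse = ", ")))
  }
  drop(S %*% v)
}
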