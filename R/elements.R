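#' Parse an elemental formula
#'
#' Turns a formula string such as `"C6H12O6"` or `"C10H12N5O13P3"` into a
#' named vector of non-negative integer element counts.
#'
#' @param formula formula string.
#' @return named integer vector, element -> count.
#' @export
#' @examples
#' parse_formula("C6H12O6")
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(integer(0))
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula))
    stop("unparseable formula: '", formula, "'", call. = FALSE)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  el <- sub("[0-9]+$", "", toks)
  ct <- as.integer(ifelse(grepl("[0-9]+$", toks),
                          sub("^[A-Za-z]+", "", toks), "1"))
  tapply(ct, el, sum)[unique(el)]
}

#' Count carbon atoms in a metabolite
#'
#' @param x a metabolite formula string, or a one-row metabolite entry from a
#'   model's metabolite table.
#' @return integer number of carbon atoms per molecule.
#' @export
#' @examples
#' carbon_count("C6H12O6")  # glucose: 6
#' carbon_count("NH4")      # ammonium: 0
carbon_count <- function(x) {
  if (is.data.frame(x)) x <- x$formula
  counts <- parse_formula(x)
  if ("C" %in% names(counts)) unname(counts[["C"]]) else 0L
}

# elemental + charge residual of one reaction; named vector, elements + "charge"
reaction_balance <- function(model, rxn_id) {
  st <- model$stoichiometry[[rxn_id]]
  met <- model$metabolites
  res <- numeric(0)
  chg <- 0
  for (i in seq_along(st)) {
    mid <- names(st)[i]
    row <- met[met$id == mid, ]
    if (nrow(row) != 1L) stop("unknown metabolite '", mid, "' in ", rxn_id)
    cnt <- parse_formula(row$formula)
    for (el in names(cnt)) {
      res[el] <- (if (el %in% names(res)) res[el] else 0) + st[i] * cnt[[el]]
    }
    chg <- chg + unname(st[i]) * row$charge
  }
  c(res, charge = chg)
}

#' Check elemental and charge balance of model reactions
#'
#' Every reaction except exchanges, biomass variants and the maintenance
#' reaction is required to conserve elements and charge. Returns the maximum
#' absolute residual per reaction so the model invariant can be asserted.
#'
#' @param model a `metabolic_model`.
#' @param tol numeric tolerance on residuals.
#' @return data.frame with `reaction` and `max_residual`, only rows above
#'   `tol` (zero rows means the model is balanced).
#' @export
check_mass_balance <- function(model, tol = 1e-9) {
  exempt <- c(model$biomass_ids, model$maintenance_id,
              model$reactions$id[model$reactions$is_exchange],
              model$pseudo_ids)
  ids <- setdiff(model$reactions$id, exempt)
  bad <- data.frame(reaction = character(0), max_residual = numeric(0))
  for (id in ids) {
    r <- reaction_balance(model, id)
    mx <- if (length(r)) max(abs(r)) else 0
    if (mx > tol)
      bad <- rbind(bad, data.frame(reaction = id, max_residual = mx))
  }
  bad
}
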