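# shared fixtures, built once per test run

TOY <- build_toy_model()

# one noiseless synthetic 13C dataset reused across estimation/UOF tests
SIM0 <- simulate_c13_dataset(TOY, synthetic_truth(6, 0, seed = 11), "fix0")

# hand-built minimal model: A_e -> A_c -> B_c -> B_e chain with a
# maintenance placeholder, for bottleneck and mapping tests
make_chain_model <- function(cap = 5) {
  mets <- data.frame(id = c("A_e", "A_c", "B_c", "B_e"),
                     name = c("A", "A", "B", "B"),
                     compartment = c("e", "c", "c", "e"),
                     formula = "C", charge = 0)
  rxns <- data.frame(
    id = c("EX_A_e", "At", "AB", "Bt", "EX_B_e", "DM"),
    name = c("A exchange", "A transport", "A to B", "B transport",
             "B exchange", "maintenance placeholder"),
    lower_bound = c(-cap, 0, 0, 0, 0, 0),
    upper_bound = c(0, 1000, 1000, 1000, 1000, 1000),
    subsystem = "", is_exchange = c(TRUE, rep(FALSE, 4), TRUE))
  st <- list(EX_A_e = c(A_e = -1), At = c(A_e = -1, A_c = 1),
             AB = c(A_c = -1, B_c = 1), Bt = c(B_c = -1, B_e = 1),
             EX_B_e = c(B_e = -1), DM = c(B_e = -1))
  metabolic_model("chain", c(e = "extracellular", c = "cytosol"),
                  mets, rxns, st, biomass_ids = "AB",
                  maintenance_id = "DM",
                  objective = list(reaction = "EX_B_e", direction = "max"),
                  pseudo_ids = "DM")
}

# random small stoichiometric model for LP oracle checks
random_lp_model <- function(seed, n_max = 8) {
  set.seed(seed)
  n <- sample(4:n_max, 1)
  m <- sample(2:4, 1)
  S <- matrix(sample(c(-2, -1, 0, 1, 2), m * n, replace = TRUE,
                     prob = c(.1, .25, .3, .25, .1)), m, n)
  for (j in seq_len(n))   # no fully disconnected reactions
    if (all(S[, j] == 0)) S[sample(m, 1), j] <- sample(c(-1, 1), 1)
  lb <- ifelse(stats::runif(n) < 0.5, -stats::runif(n, 0.5, 3), 0)
  ub <- stats::runif(n, 0.5, 4)
  ids <- paste0("r", seq_len(n))
  mets <- data.frame(id = paste0("x", seq_len(m)), name = "x",
                     compartment = "c", formula = "", charge = 0)
  rxns <- data.frame(id = ids, name = ids, lower_bound = lb,
                     upper_bound = ub, subsystem = "",
                     is_exchange = FALSE)
  st <- lapply(seq_len(n), function(j) {
    nz <- which(S[, j] != 0)
    stats::setNames(S[nz, j], paste0("x", nz))
  })
  names(st) <- ids
  metabolic_model(paste0("rand", seed), c(c = "cytosol"), mets, rxns, st,
                  biomass_ids = ids[1], maintenance_id = ids[1],
                  objective = list(reaction = sample(ids, 1),
                                   direction = "max"))
}

# brute-force vertex enumeration of {S v = 0, lb <= v <= ub}
enum_vertices <- function(A, b, lb, ub, tol = 1e-8) {
  A <- as.matrix(A); n <- ncol(A)
  r <- qr(A)$rank
  out <- list()
  for (B in utils::combn(n, r, simplify = FALSE)) {
    SB <- A[, B, drop = FALSE]
    if (qr(SB)$rank < r) next
    Nn <- setdiff(seq_len(n), B)
    k <- length(Nn)
    for (mask in 0:(2^k - 1)) {
      vN <- numeric(k)
      if (k > 0) {
        bits <- as.integer(intToBits(mask))[seq_len(k)]
        vN <- ifelse(bits == 1L, ub[Nn], lb[Nn])
      }
      rhs <- b - if (k > 0) A[, Nn, drop = FALSE] %*% vN else 0
      vB <- tryCatch(qr.solve(SB, rhs), error = function(e) NULL)
      if (is.null(vB)) next
      if (all(vB >= lb[B] - tol) && all(vB <= ub[B] + tol)) {
        v <- numeric(n); v[B] <- vB; if (k > 0) v[Nn] <- vN
        out[[length(out) + 1L]] <- v
      }
    }
  }
  if (length(out)) unique(do.call(rbind, out)) else NULL
}

# elemental residual of a reaction restricted to species with formulas,
# for checking the energetic closure of pseudo reactions
partial_balance <- function(model, rxn_id, drop_mets = character(0)) {
  st <- model$stoichiometry[[rxn_id]]
  st <- st[!names(st) %in% drop_mets]
  res <- numeric(0); chg <- 0
  for (i in seq_along(st)) {
    row <- model$metabolites[model$metabolites$id == names(st)[i], ]
    cnt <- parse_formula(row$formula)
    for (el in names(cnt))
      res[el] <- (if (el %in% names(res)) res[el] else 0) +
        st[i] * cnt[[el]]
    chg <- chg + unname(st[i]) * row$charge
  }
  c(res, charge = chg)
}
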