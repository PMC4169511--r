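## Reaction-network construction: flattened species/reaction representation
## of the streamlined and multiple-lipoplex transfection models.

.reaction <- function(reactants, products, rate_kind, rate_constant, label,
                      role, cargo = 0, release_size = 0) {
  list(reactants = reactants, products = products, rate_kind = rate_kind,
       rate_constant = rate_constant, label = label, role = role,
       cargo = cargo, release_size = release_size)
}

#' Build the transfection reaction network
#'
#' Constructs the flattened species/reaction list for either model variant.
#'
#' The streamlined variant has species `L_ex, P, E, L_in, M, G, G*` and 12
#' reactions: attachment, wash, endocytosis, lysis, endosome degradation,
#' unpacking (`L_in -> S * M`), internal-lipoplex degradation, mRNA
#' degradation, translation, maturation, and degradation of immature and
#' mature GFP.
#'
#' The multiple-lipoplex variant replaces the single pit and endosome by
#' occupancy-resolved species `P_1..P_Nmax` and `E_1..E_Nmax` (2 * N_max + 5
#' species, 3 * N_max + 18 reactions).  Attachment splits into a new-pit
#' channel `L_ex -> P_1` and join channels `L_ex + P_i -> P_{i+1}`
#' (`i < N_max`), all sharing the pit-normalised rate
#' `k_AX = k_A / (n_pits + 1)` so that the total attachment propensity stays
#' `k_A * L_ex` while pits below capacity exist (see [attach_propensity()]).
#' Lysis of `E_i` releases all `i` lipoplexes in one event; endosome
#' degradation destroys the endosome with its cargo; pits do not degrade.
#'
#' @param variant `"streamlined"` or `"multilipoplex"`.
#' @param rates a [rate_constants] object.
#' @param design an [experiment_design] object.
#' @return An object of class `lipoplex_network`: a list with elements
#'   `variant`, `species`, `reactions`, `observables` (named coefficient
#'   vectors over species: `attached`, `in_endosomes`, `mRNA`,
#'   `mature_gfp`), `rates` and `design`.
#' @export
#' @examples
#' net <- build_network("streamlined", rate_preset("streamlined_slow"),
#'                      experiment_design(L_ex0 = 200))
#' net
build_network <- function(variant = c("streamlined", "multilipoplex"),
                          rates, design) {
  if (is.character(variant) && length(variant) == 1L &&
      !variant %in% c("streamlined", "multilipoplex"))
    stop("unknown variant '", variant, "'", call. = FALSE)
  variant <- match.arg(variant)
  stopifnot(inherits(rates, "rate_constants"),
            inherits(design, "experiment_design"))
  N <- design$N_max
  if (N < 1) stop("N_max must be >= 1", call. = FALSE)
  S <- design$S

  downstream <- list(
    .reaction(c(L_in = 1), setNames(S, "M"), "mass_action_first_order",
              rates$k_U, "unpack: L_in -> S*M", "unpack",
              cargo = 1, release_size = S),
    .reaction(c(L_in = 1), NULL, "mass_action_first_order", rates$d_L,
              "degrade: L_in -> 0", "lipoplex_degradation", cargo = 1),
    .reaction(c(M = 1), NULL, "mass_action_first_order", rates$d_M,
              "degrade: M -> 0", "mRNA_degradation"),
    .reaction(c(M = 1), c(M = 1, G = 1), "mass_action_first_order",
              rates$k_TL, "translate: M -> M + G", "translation"),
    .reaction(c(G = 1), c(`G*` = 1), "mass_action_first_order", rates$k_M,
              "mature: G -> G*", "maturation"),
    .reaction(c(G = 1), NULL, "mass_action_first_order", rates$d_G,
              "degrade: G -> 0", "gfp_degradation"),
    .reaction(c(`G*` = 1), NULL, "mass_action_first_order", rates$d_G,
              "degrade: G* -> 0", "gfp_degradation")
  )

  if (variant == "streamlined") {
    species <- c("L_ex", "P", "E", "L_in", "M", "G", "G*")
    reactions <- c(list(
      .reaction(c(L_ex = 1), c(P = 1), "mass_action_first_order", rates$k_A,
                "attach: L_ex -> P", "attach", cargo = 1),
      .reaction(c(L_ex = 1), NULL, "wash", rates$k_W,
                "wash: L_ex -> 0", "wash", cargo = 1),
      .reaction(c(P = 1), c(E = 1), "mass_action_first_order", rates$k_E,
                "endocytose: P -> E", "endocytosis", cargo = 1),
      .reaction(c(E = 1), c(L_in = 1), "mass_action_first_order", rates$k_L,
                "lyse: E -> L_in", "lysis", cargo = 1),
      .reaction(c(E = 1), NULL, "mass_action_first_order", rates$d_E,
                "degrade: E -> 0", "endosome_degradation", cargo = 1)),
      downstream)
    attached <- setNames(as.numeric(species == "P"), species)
    in_endo  <- setNames(as.numeric(species == "E"), species)
  } else {
    Pn <- paste0("P_", seq_len(N)); En <- paste0("E_", seq_len(N))
    species <- c("L_ex", Pn, En, "L_in", "M", "G", "G*")
    reactions <- list(
      .reaction(c(L_ex = 1), NULL, "wash", rates$k_W,
                "wash: L_ex -> 0", "wash", cargo = 1),
      .reaction(c(L_ex = 1), c(P_1 = 1), "attach_channel", rates$k_A,
                "attach (new pit): L_ex -> P_1", "attach_new", cargo = 1))
    if (N > 1) for (i in seq_len(N - 1L)) {
      re <- setNames(c(1, 1), c("L_ex", Pn[i]))
      reactions <- c(reactions, list(
        .reaction(re, setNames(1, Pn[i + 1]), "attach_channel", rates$k_A,
                  sprintf("attach (join): L_ex + %s -> %s", Pn[i], Pn[i + 1]),
                  "attach_join", cargo = 1)))
    }
    for (i in seq_len(N)) reactions <- c(reactions, list(
      .reaction(setNames(1, Pn[i]), setNames(1, En[i]),
                "mass_action_first_order", rates$k_E,
                sprintf("endocytose: %s -> %s", Pn[i], En[i]),
                "endocytosis", cargo = i)))
    for (i in seq_len(N)) reactions <- c(reactions, list(
      .reaction(setNames(1, En[i]), setNames(i, "L_in"),
                "mass_action_first_order", rates$k_L,
                sprintf("lyse: %s -> %d L_in", En[i], i), "lysis",
                cargo = i)))
    for (i in seq_len(N)) reactions <- c(reactions, list(
      .reaction(setNames(1, En[i]), NULL, "mass_action_first_order",
                rates$d_E, sprintf("degrade: %s -> 0", En[i]),
                "endosome_degradation", cargo = i)))
    reactions <- c(reactions, downstream)
    attached <- setNames(numeric(length(species)), species)
    attached[Pn] <- seq_len(N)
    in_endo <- setNames(numeric(length(species)), species)
    in_endo[En] <- seq_len(N)
  }

  for (r in reactions) {
    sp <- c(names(r$reactants), names(r$products))
    if (!all(sp %in% species))
      stop("reaction '", r$label, "' references undeclared species",
           call. = FALSE)
  }

  structure(list(
    variant = variant, species = species, reactions = reactions,
    observables = list(
      attached = attached, in_endosomes = in_endo,
      mRNA = setNames(as.numeric(species == "M"), species),
      mature_gfp = setNames(as.numeric(species == "G*"), species)),
    rates = rates, design = design), class = "lipoplex_network")
}

#' @export
print.lipoplex_network <- function(x, ...) {
  cat(sprintf("Lipoplex transfection network ('%s' variant)\n", x$variant))
  cat(sprintf("  %d species, %d reactions; S = %d mRNA/lipoplex, N_max = %d\n",
              length(x$species), length(x$reactions), x$design$S,
              x$design$N_max))
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

## Net stoichiometry matrix (reactions x species).
network_stoich <- function(net) {
  S <- matrix(0, length(net$reactions), length(net$species),
              dimnames = list(NULL, net$species))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    for (nm in names(r$reactants)) S[j, nm] <- S[j, nm] - r$reactants[[nm]]
    for (nm in names(r$products))  S[j, nm] <- S[j, nm] + r$products[[nm]]
  }
  S
}

## Index (1-based) of the propensity-carrying reactant of each reaction.
## For attach channels this is the joined pit (or L_ex for the new-pit
## channel); for wash it is L_ex.
network_reactant_index <- function(net) {
  vapply(net$reactions, function(r) {
    nm <- names(r$reactants)
    nm <- if (length(nm) > 1L) setdiff(nm, "L_ex") else nm
    match(nm[1L], net$species)
  }, integer(1))
}

#' Pit-normalised attachment propensities
#'
#' Attachment is spread over one new-pit channel plus one channel per
#' existing pit, each running at `k_AX = k_A / (n_pits + 1)` per external
#' lipoplex.  The normalisation keeps the total attachment propensity at
#' `k_A * L_ex`, independent of how many pits have already formed (as long
#' as no pit is at capacity, whose join channel is absent).
#'
#' @param k_A attachment rate (1/h).
#' @param L_ex_count number of external lipoplexes.
#' @param n_pits_occupied number of existing (non-full) pits.
#' @return A list with `k_AX`, `n_channels`, `per_channel` (propensity of
#'   each channel, 1/h) and `total`.
#' @export
#' @examples
#' attach_propensity(0.27, 10, 2)  # 3 channels of 0.9/h, total 2.7/h
attach_propensity <- function(k_A, L_ex_count, n_pits_occupied) {
  stopifnot(k_A >= 0, L_ex_count >= 0, n_pits_occupied >= 0)
  k_AX <- k_A / (n_pits_occupied + 1)
  n_ch <- n_pits_occupied + 1
  per <- k_AX * L_ex_count
  list(k_AX = k_AX, n_channels = n_ch, per_channel = rep(per, n_ch),
       total = per * n_ch)
}

#' Time-dependent washing rate
#'
#' Zero during incubation, jumps to `k_W_high` at the incubation time
#' (boundary inclusive).
#'
#' @param t time (h); vectorised.
#' @param t_inc incubation time (h).
#' @param k_W_high post-wash rate (1/h).
#' @export
#' @examples
#' wash_rate(c(0.5, 1, 2), t_inc = 1, k_W_high = 1e6)
wash_rate <- function(t, t_inc, k_W_high) {
  stopifnot(all(t >= 0))
  ifelse(t >= t_inc, k_W_high, 0)
}

## ---- exact big-integer helpers (base 1e4 digit vectors, little-endian) ----

.big_from_int <- function(n) {
  d <- integer(0)
  n <- as.integer(n)
  while (n > 0L) { d <- c(d, n %% 10000L); n <- n %/% 10000L }
  if (length(d) == 0L) d <- 0L
  d
}

.big_mul <- function(a, b) {
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) res[i:(i + length(b) - 1L)] <-
      res[i:(i + length(b) - 1L)] + a[i] * b
  carry <- 0
  for (i in seq_along(res)) {
    v <- res[i] + carry
    res[i] <- v %% 10000
    carry <- floor(v / 10000)
  }
  while (carry > 0) { res <- c(res, carry %% 10000); carry <- carry %/% 10000 }
  while (length(res) > 1 && res[length(res)] == 0)
    res <- res[-length(res)]
  res
}

.big_to_string <- function(d) {
  n <- length(d)
  paste0(d[n], paste0(sprintf("%04d", rev(d[-n])), collapse = ""))
}

#' Count of distinct endosome states under an ordered size listing
#'
#' When each of up to `N_max` lipoplexes in an endosome can take one of
#' `size_states` sizes, listing every combination as its own species needs
#' `size_states ^ N_max` variables.  The count is computed with exact
#' big-integer arithmetic (it overflows doubles already for the realistic
#' 175 sizes and capacity 10, where it is about 2.7e22) and quantifies why
#' the fixed-size simplification is needed before every endosome state can
#' be enumerated.
#'
#' @param size_states number of distinct lipoplex sizes (e.g. 175 for
#'   270–445 mRNA, fixed to 1 under the equal-size simplification).
#' @param N_max endosome capacity.
#' @return An object of class `big_count` with fields `string` (exact
#'   decimal representation), `log10` and `approx` (double, possibly `Inf`).
#' @export
#' @examples
#' count_full_nested_species(175, 10)
count_full_nested_species <- function(size_states, N_max) {
  stopifnot(size_states >= 1, N_max >= 1)
  size_states <- as.integer(size_states); N_max <- as.integer(N_max)
  acc <- .big_from_int(1L)
  base <- .big_from_int(size_states)
  for (i in seq_len(N_max)) acc <- .big_mul(acc, base)
  s <- .big_to_string(acc)
  structure(list(string = s, log10 = N_max * log10(size_states),
                 approx = size_states^as.numeric(N_max)),
            class = "big_count")
}

#' @export
print.big_count <- function(x, ...) {
  cat(sprintf("%s (~1e%.2f)\n", x$string, x$log10))
  invisible(x)
}

## Exact comparison of two big_count objects: -1, 0, 1.
compare_big_count <- function(a, b) {
  sa <- a$string; sb <- b$string
  if (nchar(sa) != nchar(sb)) return(sign(nchar(sa) - nchar(sb)))
  if (sa == sb) 0L else if (sa < sb) -1L else 1L
}
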