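#' @importFrom rlang abort %||%
#' @importFrom tibble tibble as_tibble
NULL

# Organic-subset default valences (daylight rules); bracket atoms carry an
# explicit hydrogen count instead.
.default_valence <- c(
  B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
  F = 1, Cl = 1, Br = 1, I = 1
)

.atomic_number <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9,
  Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17,
  Ar = 18, K = 19, Ca = 20, Ti = 22, Cr = 24, Mn = 25, Fe = 26, Co = 27,
  Ni = 28, Cu = 29, Zn = 30, As = 33, Se = 34, Br = 35, Pd = 46, Ag = 47,
  Sn = 50, I = 53, Cs = 55, Pt = 78, Au = 79
)

parse_error <- function(msg, smiles) {
  abort(
    sprintf("SMILES parse error: %s [in %s]", msg, smiles),
    class = "hteyield_parse_error",
    smiles = smiles
  )
}

# Tokenizes and parses a daylight-style SMILES string into atom and bond
# tables. Stereochemistry and isotopes are accepted but discarded; '.' keeps
# fragments in one graph with no connecting bond.
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    parse_error("empty or non-string input", as.character(smiles)[1] %||% NA)
  }
  s <- trimws(smiles)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)

  element <- character()
  charge <- integer()
  aromatic <- logical()
  explicit_h <- integer()   # NA => implicit
  bond_i <- integer(); bond_j <- integer()
  bond_order <- numeric(); bond_arom <- logical()

  prev <- NA_integer_          # atom the next bond attaches to
  stack <- integer()           # open branch points
  pending_bond <- NA_character_
  ring <- list()               # closure digit -> list(atom, bond)

  add_atom <- function(el, ch, ar, eh) {
    element[[length(element) + 1L]] <<- el
    charge[[length(charge) + 1L]] <<- ch
    aromatic[[length(aromatic) + 1L]] <<- ar
    explicit_h[[length(explicit_h) + 1L]] <<- eh
    length(element)
  }
  add_bond <- function(i, j, sym, ar_i, ar_j) {
    if (i == j) parse_error("self-bond", s)
    if (is.na(sym)) {
      if (ar_i && ar_j) { ord <- 1.5; ar <- TRUE } else { ord <- 1; ar <- FALSE }
    } else {
      ord <- switch(sym, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5,
                    "/" = 1, "\\" = 1,
                    parse_error(sprintf("unknown bond '%s'", sym), s))
      ar <- identical(sym, ":")
    }
    bond_i[[length(bond_i) + 1L]] <<- min(i, j)
    bond_j[[length(bond_j) + 1L]] <<- max(i, j)
    bond_order[[length(bond_order) + 1L]] <<- ord
    bond_arom[[length(bond_arom) + 1L]] <<- ar
  }
  connect <- function(idx) {
    if (!is.na(prev)) {
      add_bond(prev, idx, pending_bond, aromatic[prev], aromatic[idx])
    }
    pending_bond <<- NA_character_
    prev <<- idx
  }
  close_ring <- function(key) {
    if (is.na(prev)) parse_error("ring closure before any atom", s)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, bond = pending_bond)
      pending_bond <<- NA_character_
    } else {
      other <- ring[[key]]
      sym <- pending_bond
      if (is.na(sym) && !is.na(other$bond)) sym <- other$bond
      add_bond(other$atom, prev, sym, aromatic[other$atom], aromatic[prev])
      ring[[key]] <<- NULL
      pending_bond <<- NA_character_
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) parse_error("unclosed bracket atom", s)
      body <- substr(s, i + 1L, j - 1L)
      at <- parse_bracket_atom(body, s)
      idx <- add_atom(at$element, at$charge, at$aromatic, at$hcount)
      connect(idx)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      idx <- add_atom(paste0(ch, chars[i + 1L]), 0L, FALSE, NA_integer_)
      connect(idx)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      idx <- add_atom(ch, 0L, FALSE, NA_integer_)
      connect(idx)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- add_atom(toupper(ch), 0L, TRUE, NA_integer_)
      connect(idx)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) parse_error("truncated %nn ring closure", s)
      close_ring(substr(s, i + 1L, i + 2L))
      i <- i + 3L
    } else if (ch == "(") {
      if (is.na(prev)) parse_error("branch before any atom", s)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) parse_error("unmatched ')'", s)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- NA_character_
      i <- i + 1L
    } else {
      parse_error(sprintf("unexpected character '%s'", ch), s)
    }
  }
  if (length(stack) > 0L) parse_error("unmatched '('", s)
  if (length(ring) > 0L) parse_error("unclosed ring bond", s)
  if (length(element) == 0L) parse_error("no atoms", s)

  atoms <- tibble(
    element = element, charge = charge, aromatic = aromatic,
    explicit_h = explicit_h
  )
  bonds <- tibble(
    i = bond_i, j = bond_j, order = bond_order, aromatic = bond_arom
  )
  if (anyDuplicated(paste(bonds$i, bonds$j))) {
    parse_error("duplicate bond between one atom pair", s)
  }
  list(atoms = atoms, bonds = bonds)
}

parse_bracket_atom <- function(body, smiles) {
  rest <- sub("^[0-9]*", "", body)  # isotope discarded
  m <- regmatches(rest, regexpr("^([A-Z][a-z]?|[bcnops])", rest))
  if (length(m) == 0L) parse_error(sprintf("bad bracket atom [%s]", body), smiles)
  sym <- m
  rest <- substr(rest, nchar(sym) + 1L, nchar(rest))
  ar <- sym %in% c("b", "c", "n", "o", "p", "s")
  el <- if (ar) toupper(sym) else sym
  rest <- sub("^@{1,2}", "", rest)  # chirality discarded
  hc <- 0L
  hm <- regmatches(rest, regexpr("^H[0-9]*", rest))
  if (length(hm) == 1L) {
    hc <- if (nchar(hm) == 1L) 1L else as.integer(substr(hm, 2L, nchar(hm)))
    rest <- substr(rest, nchar(hm) + 1L, nchar(rest))
  }
  chg <- 0L
  cm <- regmatches(rest, regexpr("^(\\+{1,3}|-{1,3})([0-9]+)?", rest))
  if (length(cm) == 1L && nzchar(cm)) {
    sign <- if (substr(cm, 1L, 1L) == "+") 1L else -1L
    digits <- gsub("[+-]", "", cm)
    chg <- if (nzchar(digits)) sign * as.integer(digits) else sign * nchar(gsub("[0-9]", "", cm))
    rest <- substr(rest, nchar(cm) + 1L, nchar(rest))
  }
  rest <- sub("^:[0-9]+", "", rest)  # atom-map class discarded
  if (nzchar(rest)) parse_error(sprintf("trailing '%s' in bracket atom [%s]", rest, body), smiles)
  list(element = el, charge = chg, aromatic = ar, hcount = hc)
}

# Implicit hydrogen count under default valences; aromatic bonds contribute
# 1.5 to the bond-order sum. Charged organic-subset atoms shift valence by
# the formal charge (e.g. [O-] 1, [N+] 4). Bracket atoms keep their explicit
# count.
implicit_hydrogens <- function(atoms, bonds) {
  n <- nrow(atoms)
  bsum <- numeric(n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      o <- bonds$order[k]
      bsum[bonds$i[k]] <- bsum[bonds$i[k]] + o
      bsum[bonds$j[k]] <- bsum[bonds$j[k]] + o
    }
  }
  h <- integer(n)
  for (a in seq_len(n)) {
    if (!is.na(atoms$explicit_h[a])) {
      h[a] <- atoms$explicit_h[a]
    } else {
      v <- .default_valence[[atoms$element[a]]] %||% 0
      v <- max(0, v + atoms$charge[a])
      h[a] <- max(0L, as.integer(v - ceiling(bsum[a] - 1e-9)))
    }
  }
  h
}
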