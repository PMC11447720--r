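#' @importFrom dplyr mutate select all_of bind_rows arrange group_by summarise
#'   ungroup filter n left_join distinct pull rename row_number
#' @importFrom purrr map map_chr map_dbl map_int map_lgl imap walk
#' @importFrom utils read.csv write.csv
NULL

data_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "hteyield_data_error")
}

is_none_cell <- function(x) {
  is.na(x) | !nzchar(trimws(x)) | tolower(trimws(x)) == "none"
}

#' Assemble a reaction dataset from a table of role SMILES and yields
#'
#' A reaction dataset couples a tidy reaction table (one row per reaction,
#' one SMILES column per reaction role, a percent yield column) with a
#' registry of the distinct structures appearing under each role and a
#' cache of their parsed molecular graphs. Registry lookups are by
#' canonical structure, so two input strings describing the same molecule
#' are the same registry entry. The literal cell value `"none"`
#' (case-insensitive) or an empty cell marks an absent component.
#'
#' @param table A data frame with one column per role plus a yield column.
#' @param roles Character vector of role labels; `names(roles)` gives the
#'   corresponding column names (defaults to the labels themselves). Order
#'   fixes the role vocabulary.
#' @param yield_column Name of the numeric yield column (percent scale).
#' @param id_column Optional reaction-id column; ids are generated when
#'   absent.
#' @param clamp_yields If `TRUE`, yields outside \[0, 100\] are clamped to
#'   the range instead of rejected.
#' @return An object of class `reaction_dataset`: list with `table`
#'   (tibble: `reaction_id`, one canonical-SMILES column per role, `yield`),
#'   `roles`, `registry` (named list role -> canonical structures) and
#'   `graphs` (named list canonical SMILES -> `mol_graph`).
#' @export
reaction_dataset <- function(table, roles, yield_column = "yield",
                             id_column = NULL, clamp_yields = FALSE) {
  table <- as_tibble(table)
  role_cols <- names(roles) %||% roles
  if (is.null(names(roles))) names(roles) <- roles
  for (col in c(role_cols, yield_column)) {
    if (!col %in% names(table)) data_error("missing column '%s'", col)
  }
  yields <- table[[yield_column]]
  if (is.character(yields)) {
    conv <- suppressWarnings(as.numeric(yields))
    bad <- which(is.na(conv) & !is.na(yields))
    if (length(bad) > 0) {
      data_error("non-numeric yield '%s' in row %d", yields[bad[1]], bad[1])
    }
    yields <- conv
  }
  if (anyNA(yields) || any(!is.finite(yields))) {
    data_error("missing or non-finite yield in row %d",
               which(is.na(yields) | !is.finite(yields))[1])
  }
  if (clamp_yields) {
    yields <- pmin(100, pmax(0, yields))
  } else if (any(yields < 0 | yields > 100)) {
    data_error("yield outside [0, 100] in row %d (use clamp_yields = TRUE to clamp)",
               which(yields < 0 | yields > 100)[1])
  }

  graphs <- new.env(parent = emptyenv())   # canonical smiles -> mol_graph
  canon_cache <- new.env(parent = emptyenv())  # raw string -> canonical
  canon_of <- function(raw, row, col) {
    key <- paste0("s", raw)
    hit <- canon_cache[[key]]
    if (!is.null(hit)) return(hit)
    g <- tryCatch(graph_from_smiles(raw), error = function(e) {
      data_error("bad SMILES '%s' in row %d, column '%s'", raw, row, col)
    })
    canon_cache[[key]] <- g$canonical_smiles
    if (is.null(graphs[[g$canonical_smiles]])) graphs[[g$canonical_smiles]] <- g
    g$canonical_smiles
  }

  out <- tibble(.rows = nrow(table))
  out$reaction_id <- if (!is.null(id_column)) {
    as.character(table[[id_column]])
  } else {
    sprintf("rxn%04d", seq_len(nrow(table)))
  }
  for (col in role_cols) {
    role <- unname(roles[[col]])
    raw <- as.character(table[[col]])
    canon <- rep(NA_character_, length(raw))
    for (r in seq_along(raw)) {
      if (!is_none_cell(raw[r])) canon[r] <- canon_of(trimws(raw[r]), r, col)
    }
    out[[role]] <- canon
  }
  out$yield <- as.numeric(yields)

  registry <- lapply(unname(roles), function(role) {
    sort(unique(out[[role]][!is.na(out[[role]])]))
  })
  names(registry) <- unname(roles)

  structure(
    list(table = out, roles = unname(roles), registry = registry,
         graphs = as.list(graphs)),
    class = "reaction_dataset"
  )
}

#' @export
print.reaction_dataset <- function(x, ...) {
  cat(sprintf("<reaction_dataset> %d reactions, roles: %s\n",
              nrow(x$table), paste(x$roles, collapse = ", ")))
  sizes <- map_int(x$registry, length)
  cat("  registry sizes:",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Number of reactions in a dataset
#' @param ds A `reaction_dataset`.
#' @export
n_reactions <- function(ds) nrow(ds$table)

#' Read a reaction table from CSV
#'
#' Reads a UTF-8, comma-separated reaction table with a header row: one
#' SMILES column per reaction role and one numeric percent-yield column.
#' Row order is preserved; `"none"` or empty cells mark absent components.
#'
#' @inheritParams reaction_dataset
#' @param path CSV file path.
#' @param role_columns Named character vector mapping column names to role
#'   labels, e.g. `c(halide_smiles = "aryl_halide", ...)`; an unnamed vector
#'   means columns are already named after the roles.
#' @return A [reaction_dataset()].
#' @export
read_reaction_table <- function(path, role_columns, yield_column = "yield",
                                id_column = NULL, clamp_yields = FALSE) {
  if (!file.exists(path)) data_error("no such file: %s", path)
  tab <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                            check.names = FALSE, fileEncoding = "UTF-8"))
  reaction_dataset(tab, role_columns, yield_column = yield_column,
                   id_column = id_column, clamp_yields = clamp_yields)
}

#' Write a reaction dataset back to CSV
#'
#' Structures are written as canonical SMILES and absent components as
#' `"none"`; yields are written exactly. Reading the file back yields a
#' dataset whose structures and yields match the original (structures up to
#' canonicalization, which is idempotent).
#'
#' @param ds A `reaction_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(ds, path) {
  out <- ds$table
  for (role in ds$roles) {
    out[[role]] <- ifelse(is.na(out[[role]]), "none", out[[role]])
  }
  # full-precision yields so read -> write -> read is exact
  out$yield <- sprintf("%.17g", out$yield)
  write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Components of one reaction
#'
#' @param ds A `reaction_dataset`.
#' @param i Row index.
#' @return Named list (one entry per role) of `mol_graph` or `mol_absent`.
#' @export
reaction_components <- function(ds, i) {
  stopifnot(i >= 1, i <= nrow(ds$table))
  comps <- lapply(ds$roles, function(role) {
    s <- ds$table[[role]][i]
    if (is.na(s)) mol_absent() else ds$graphs[[s]]
  })
  names(comps) <- ds$roles
  comps
}

#' Registry of distinct structures per role, as a tibble
#' @param ds A `reaction_dataset`.
#' @return Tibble with columns `role`, `structure` (canonical SMILES).
#' @export
dataset_registry <- function(ds) {
  bind_rows(imap(ds$registry, function(st, role) {
    tibble(role = role, structure = st)
  }))
}

#' Subset a dataset by reaction indices
#'
#' Keeps the selected reactions and recomputes the per-role registry; the
#' parsed-graph cache is shared (graphs are immutable). Typically used to
#' materialize the training partition of a `split_result`.
#'
#' @param ds A `reaction_dataset`.
#' @param idx Integer reaction indices.
#' @return A `reaction_dataset`.
#' @export
subset_dataset <- function(ds, idx) {
  out <- ds
  out$table <- ds$table[idx, , drop = FALSE]
  out$registry <- lapply(ds$roles, function(role) {
    sort(unique(out$table[[role]][!is.na(out$table[[role]])]))
  })
  names(out$registry) <- ds$roles
  out
}

# Indices of reactions containing any of the given structures in a role.
reactions_with <- function(ds, role, structures) {
  if (!role %in% ds$roles) data_error("unknown role '%s'", role)
  which(ds$table[[role]] %in% structures)
}
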