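#' Parse a molecular formula into element counts
#'
#' Handles simple Hill-style formulas such as `"C10H20O"`. Only single-letter
#' and two-letter element symbols with optional integer counts are supported;
#' no parentheses (the terpene fixtures and typical config files do not need
#' them).
#'
#' @param formula Character vector of molecular formulas.
#' @return A list of named integer vectors (element -> count).
#' @export
#' @examples
#' parse_formula("C10H20O")
parse_formula <- function(formula) {
  lapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) {
      return(setNames(integer(0), character(0)))
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    pieces <- regmatches(f, list(m))[[1]]
    if (!nzchar(paste(pieces, collapse = "")) ||
        nchar(paste(pieces, collapse = "")) != nchar(f)) {
      abort(paste0("cannot parse formula '", f, "'"), class = "eutectr_format_error")
    }
    el <- sub("[0-9]*$", "", pieces)
    n <- as.integer(ifelse(grepl("[0-9]+$", pieces), sub("^[A-Za-z]+", "", pieces), "1"))
    tapply(n, el, sum)[unique(el)]
  })
}

#' Molar mass from a molecular formula
#'
#' Uses 2021 IUPAC standard atomic weights for the elements that occur in
#' the shipped fixtures (C, H, O, N, S).
#'
#' @param formula Character vector of molecular formulas.
#' @return Numeric vector of molar masses in g/mol.
#' @export
#' @examples
#' formula_mw("C10H20O") # menthol, 156.27
formula_mw <- function(formula) {
  weights <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, S = 32.06)
  vapply(parse_formula(formula), function(counts) {
    unknown <- setdiff(names(counts), names(weights))
    if (length(unknown)) {
      abort(paste0("no atomic weight for element(s): ", paste(unknown, collapse = ", ")),
            class = "eutectr_validation_error")
    }
    sum(weights[names(counts)] * counts)
  }, numeric(1))
}

new_compound_tbl <- function(name, formula, mw, t_fus_K, dh_fus_kJ_mol,
                             unifac_groups, ljr_groups, t_b_K = NA_real_) {
  stopifnot(all(mw > 0), all(t_fus_K > 0), all(dh_fus_kJ_mol > 0))
  tibble(
    name = name, formula = formula, mw = mw,
    t_fus_K = t_fus_K, dh_fus_kJ_mol = dh_fus_kJ_mol, t_b_K = t_b_K,
    unifac_groups = unifac_groups, ljr_groups = ljr_groups
  )
}

#' Built-in terpene compound fixtures
#'
#' The four terpenes of the study with their published melting temperatures
#' and enthalpies of fusion, molar masses derived from the molecular formula,
#' and group decompositions for the UNIFAC and Lydersen-Joback-Reid
#' group-contribution methods.
#'
#' Enthalpies of fusion are stored in kJ/mol. The published data table labels
#' the column J/mol, but the magnitudes (13.62 for menthol) only reproduce the
#' published ideal eutectic points under the kJ/mol reading; every consumer of
#' `dh_fus_kJ_mol` multiplies by 1000 at the point of use.
#'
#' The group decompositions are atom-balanced choices made here (the source
#' study does not list its assignments); they are data, not code, and can be
#' edited via the YAML config shipped in `extdata/terpenes.yaml`.
#'
#' @return A tibble with one row per compound and list-columns
#'   `unifac_groups` and `ljr_groups` holding named counts.
#' @export
#' @examples
#' terpene_compounds()
terpene_compounds <- function() {
  read_compounds(extdata_path("terpenes.yaml"))
}

#' Built-in binary-system fixtures
#'
#' The four studied binary systems with the mole fraction `x_i` of the
#' first-listed component (menthol or thymol), matching the published
#' preparation ratios (7:3, 3:2, 7:3, 1:1).
#'
#' @return A tibble with columns `label`, `comp_i`, `comp_j`, `x_i`.
#' @export
terpene_systems <- function() {
  cfg <- yaml::read_yaml(extdata_path("terpenes.yaml"))
  bind_rows(lapply(cfg$systems, function(s) {
    tibble(label = s$label, comp_i = s$comp_i, comp_j = s$comp_j, x_i = s$x_i)
  }))
}

#' Thermal records of the prepared eutectic systems
#'
#' Degradation temperature (TGA), crystallization and glass-transition
#' temperatures and crystallization enthalpy (DSC) measured for each system
#' near its eutectic composition. Stored as reference fixtures; they do not
#' enter any computation.
#'
#' @return A tibble with columns `label`, `t_d_K`, `t_cr_K`, `dh_cr_J_g`, `t_g_K`.
#' @export
terpene_thermal <- function() {
  out <- tibble(
    label = c("Men:Bor", "Men:Cam", "Thy:Bor", "Thy:Cam"),
    t_d_K = c(366.02, 358.29, 355.04, 370.74),
    t_cr_K = c(254.08, 239.92, 284.64, 260.69),
    dh_cr_J_g = c(21.17, 28.60, 0.098, 0.077),
    t_g_K = c(223.03, 196.98, 215.17, 194.23)
  )
  stopifnot(all(out$t_g_K < out$t_cr_K), all(out$t_cr_K < out$t_d_K))
  out
}

#' Experimental and published-theoretical properties of the four systems
#'
#' Measured density, surface tension and refractive index at 298 K together
#' with the theoretical values printed alongside them in the source study.
#' These are comparison fixtures used for relative-error reproduction.
#'
#' @return A long tibble with columns `label`, `property`, `experimental`,
#'   `theoretical_published`.
#' @export
terpene_measured_properties <- function() {
  tidyr::expand_grid(
    label = c("Men:Bor", "Men:Cam", "Thy:Bor", "Thy:Cam"),
    property = c("density_g_mL", "surface_tension_mN_m", "refractive_index")
  ) |>
    arrange(.data$property) |>
    mutate(
      experimental = c(
        0.9152, 0.9178, 0.9716, 0.9675,       # density
        1.4670, 1.4635, 1.5105, 1.4970,       # refractive index
        29.04, 29.41, 31.75, 30.35            # surface tension
      ),
      theoretical_published = c(
        1.1116, 1.1063, 1.1500, 1.1350,
        1.4708, 1.4671, 1.4795, 1.4731,
        25.37, 23.25, 29.19, 32.25
      )
    ) |>
    arrange(.data$label)
}

as_group_list <- function(x) {
  if (is.null(x) || !length(x)) {
    return(setNames(numeric(0), character(0)))
  }
  unlist(x)
}

#' Read compound definitions from a YAML or JSON config file
#'
#' Each record needs `name`, `formula` (or `mw`), `t_fus_K` and
#' `dh_fus_kJ_per_mol`; group maps default to empty when absent. When both a
#' formula and group maps are present, the implied atom counts are checked
#' against the formula and a validation error names the offending compound
#' and element on mismatch.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A compound tibble (see [terpene_compounds()]).
#' @export
read_compounds <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "eutectr_format_error")
  }
  cfg <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) {
      abort(paste0("cannot parse '", path, "': ", conditionMessage(e)),
            class = "eutectr_format_error")
    }
  )
  records <- cfg$compounds %||% cfg
  if (!length(records)) {
    return(new_compound_tbl(character(0), character(0), numeric(0), numeric(0),
                            numeric(0), list(), list()))
  }
  rows <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    for (field in c("name", "t_fus_K", "dh_fus_kJ_per_mol")) {
      if (is.null(rec[[field]])) {
        abort(paste0("record ", i, ": missing field '", field, "'"),
              class = "eutectr_format_error")
      }
    }
    if (is.null(rec$formula) && is.null(rec$mw)) {
      abort(paste0("record ", i, " ('", rec$name, "'): needs 'formula' or 'mw'"),
            class = "eutectr_format_error")
    }
    mw <- if (!is.null(rec$mw)) as.numeric(rec$mw) else formula_mw(rec$formula)
    new_compound_tbl(
      name = rec$name, formula = rec$formula %||% NA_character_, mw = mw,
      t_fus_K = as.numeric(rec$t_fus_K),
      dh_fus_kJ_mol = as.numeric(rec$dh_fus_kJ_per_mol),
      t_b_K = if (!is.null(rec$t_b_K)) as.numeric(rec$t_b_K) else NA_real_,
      unifac_groups = list(as_group_list(rec$unifac_groups)),
      ljr_groups = list(as_group_list(rec$ljr_groups))
    )
  })
  compounds <- bind_rows(rows)
  report <- validate_group_assignment(compounds)
  bad <- filter(report, !.data$ok)
  if (nrow(bad)) {
    first <- bad[1, ]
    abort(paste0("atom balance violated for compound '", first$name, "', element ",
                 first$element, " (", first$group_system, " groups): formula has ",
                 first$formula_count, ", groups imply ", first$group_count),
          class = "eutectr_validation_error")
  }
  compounds
}

#' Write compound definitions to a YAML config file
#'
#' Inverse of [read_compounds()]; a write/read round trip reproduces all
#' fields.
#'
#' @param compounds A compound tibble.
#' @param path Output file path (YAML).
#' @return `path`, invisibly.
#' @export
write_compounds <- function(compounds, path) {
  records <- lapply(seq_len(nrow(compounds)), function(i) {
    row <- compounds[i, ]
    rec <- list(
      name = row$name, formula = row$formula, mw = row$mw,
      t_fus_K = row$t_fus_K, dh_fus_kJ_per_mol = row$dh_fus_kJ_mol
    )
    if (!is.na(row$t_b_K)) rec$t_b_K <- row$t_b_K
    ug <- row$unifac_groups[[1]]
    lg <- row$ljr_groups[[1]]
    if (length(ug)) rec$unifac_groups <- as.list(ug)
    if (length(lg)) rec$ljr_groups <- as.list(lg)
    rec
  })
  yaml::write_yaml(list(compounds = records), path)
  invisible(path)
}

group_atom_table <- function(system = c("unifac", "ljr")) {
  system <- match.arg(system)
  tab <- if (system == "unifac") {
    read_table_file("unifac_subgroups.csv") |> rename(group = "subgroup")
  } else {
    read_table_file("ljr_groups.csv")
  }
  select(tab, "group", "n_C", "n_H", "n_O")
}

#' Check group decompositions against the molecular formula
#'
#' For each compound and each non-empty group map, sums the C/H/O atoms
#' implied by the group counts and compares them with the molecular formula.
#' The report carries per-element residuals (formula minus group-implied);
#' a compound passes iff all residuals are zero.
#'
#' @param compounds A compound tibble.
#' @return A tibble with columns `name`, `group_system`, `element`,
#'   `formula_count`, `group_count`, `residual`, `ok`.
#' @export
#' @examples
#' validate_group_assignment(terpene_compounds())
validate_group_assignment <- function(compounds) {
  atoms <- list(unifac = group_atom_table("unifac"), ljr = group_atom_table("ljr"))
  out <- list()
  for (i in seq_len(nrow(compounds))) {
    row <- compounds[i, ]
    if (is.na(row$formula)) next
    counts <- parse_formula(row$formula)[[1]]
    for (sys in c("unifac", "ljr")) {
      gmap <- row[[paste0(sys, "_groups")]][[1]]
      if (!length(gmap)) next
      tab <- atoms[[sys]]
      unknown <- setdiff(names(gmap), tab$group)
      if (length(unknown)) {
        abort(paste0("compound '", row$name, "': unknown ", sys, " group(s): ",
                     paste(unknown, collapse = ", ")),
              class = "eutectr_validation_error")
      }
      idx <- match(names(gmap), tab$group)
      for (el in c("C", "H", "O")) {
        implied <- sum(gmap * tab[[paste0("n_", el)]][idx])
        have <- if (el %in% names(counts)) counts[[el]] else 0L
        out[[length(out) + 1L]] <- tibble(
          name = row$name, group_system = sys, element = el,
          formula_count = as.numeric(have), group_count = implied,
          residual = as.numeric(have) - implied, ok = (as.numeric(have) - implied) == 0
        )
      }
    }
  }
  if (!length(out)) {
    abort("no compound has both a formula and a non-empty group map",
          class = "eutectr_validation_error")
  }
  bind_rows(out)
}

#' Extract a two-row compound pair for a binary system
#'
#' @param compounds A compound tibble.
#' @param comp_i,comp_j Compound names; `comp_i` is the component whose mole
#'   fraction `x` refers to throughout the package.
#' @return A two-row compound tibble ordered (i, j).
#' @export
#' @examples
#' system_pair(terpene_compounds(), "menthol", "borneol")
system_pair <- function(compounds, comp_i, comp_j) {
  if (identical(comp_i, comp_j)) {
    abort("a binary system needs two distinct compounds",
          class = "eutectr_validation_error")
  }
  idx <- match(c(comp_i, comp_j), compounds$name)
  if (anyNA(idx)) {
    abort(paste0("compound(s) not found: ",
                 paste(c(comp_i, comp_j)[is.na(idx)], collapse = ", ")),
          class = "eutectr_validation_error")
  }
  compounds[idx, ]
}
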