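# Declarative geometry of the seven RING finger types. Everything downstream
# (scanner, simulator, alignment) is driven by this table, never by
# hard-coded patterns.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# substitutions admissible at a zinc-ligand slot only with a deviation flag
TOLERATED_UNIVERSE <- c("H", "D", "S", "T", "G")

RING_TYPE_NAMES <- c("RING-H2", "RING-HC", "RING-v", "RING-C2",
                     "RING-D", "RING-S/T", "RING-G")

# spacer-4 range each named type must carry (validated on load)
SPACER4_RULES <- list(
  "RING-H2" = c(2L, 3L), "RING-HC" = c(2L, 3L), "RING-D" = c(2L, 3L),
  "RING-S/T" = c(2L, 3L), "RING-C2" = c(4L, 5L), "RING-v" = c(7L, 7L),
  "RING-G" = c(2L, 3L)
)

#' Load a RING type table
#'
#' Reads a declarative definition of RING finger types: for each type, eight
#' zinc-ligand slots (allowed residues plus substitutions tolerated with a
#' deviation flag) and seven inter-ligand spacer ranges (with optional
#' extension allowances, also flagged). With no argument the canonical table
#' shipped with the package is loaded: seven types whose identity is carried
#' by ligand slots 4 and 5 (H2 = H,H; HC = H,C; v = C,H; C2 = C,C; D = H,D;
#' S/T = H,S-or-T; G = H,G), cysteine elsewhere, and the canonical spacing
#' C-x2-C-x(9-39)-C-x(1-3)-[45]-x(type)-[5]-x2-C-x(4-48)-C-x2-C.
#'
#' @param path Path to a YAML type-table config; `NULL` loads the packaged
#'   default.
#' @param allow_subset Permit configs defining fewer than the seven canonical
#'   types (used e.g. to restrict analyses to one type).
#' @return A validated `ring_type_table` object.
#' @export
#' @examples
#' tab <- load_type_table()
#' names(tab$defs)
load_type_table <- function(path = NULL, allow_subset = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "ring_types.yaml", package = "ringcat")
  }
  if (!file.exists(path)) stop("type-table config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$types) || !length(cfg$types)) {
    stop("configuration error: no 'types' section in ", path)
  }
  defaults <- cfg$defaults
  defs <- lapply(names(cfg$types), function(nm) {
    parse_type_def(nm, cfg$types[[nm]], defaults)
  })
  names(defs) <- names(cfg$types)
  tab <- structure(
    list(defs = defs, version = cfg$version %||% "unversioned"),
    class = "ring_type_table"
  )
  validate_type_table(tab, allow_subset = allow_subset)
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_type_def <- function(name, spec, defaults) {
  if (!is.null(spec$slots)) {
    # full form: 8 explicit slot entries
    slots <- lapply(spec$slots, function(s) {
      list(allowed = as.character(s$allowed %||% character()),
           tolerated = as.character(s$tolerated %||% character()))
    })
  } else {
    # compact form: slot4/slot5 carry the type identity, C elsewhere;
    # boundary slots 1-2 and 7-8 take the default tolerated set
    bt <- as.character(defaults$boundary_tolerated %||% character())
    slot <- function(allowed, tolerated = character()) {
      list(allowed = as.character(allowed), tolerated = tolerated)
    }
    if (is.null(spec$slot4) || is.null(spec$slot5)) {
      stop("configuration error: type ", name,
           " supplies neither 'slots' nor slot4/slot5")
    }
    slots <- list(
      slot("C", bt), slot("C", bt), slot("C"),
      slot(spec$slot4), slot(spec$slot5), slot("C"),
      slot("C", bt), slot("C", bt)
    )
  }
  if (!is.null(spec$spacers)) {
    spacers <- lapply(spec$spacers, function(s) {
      list(min = as.integer(s$min), max = as.integer(s$max),
           ext = as.integer(s$ext %||% 0L))
    })
  } else {
    spacers <- lapply(defaults$spacers, function(s) {
      list(min = as.integer(s$min), max = as.integer(s$max),
           ext = as.integer(s$ext %||% 0L))
    })
    if (!is.null(spec$spacer4)) {
      spacers[[4]]$min <- as.integer(spec$spacer4$min)
      spacers[[4]]$max <- as.integer(spec$spacer4$max)
    }
  }
  list(name = name, priority = as.integer(spec$priority %||% NA_integer_),
       slots = slots, spacers = spacers)
}

#' Validate a RING type table
#'
#' Checks the structural invariants: unique names and priorities, eight slots
#' per type with allowed residues in the 20-letter alphabet and tolerated
#' substitutions within \{H, D, S, T, G\}, seven well-formed spacer ranges,
#' the type-specific spacer-4 rule for the named canonical types, and the
#' central-core span (ligands 3 through 6) lying in [9, 16] for every allowed
#' spacer combination.
#'
#' @param table A `ring_type_table`.
#' @param allow_subset Permit fewer than the seven canonical types.
#' @return The table, invisibly; errors name the offending type/slot.
#' @export
validate_type_table <- function(table, allow_subset = FALSE) {
  stopifnot(inherits(table, "ring_type_table"))
  defs <- table$defs
  nms <- names(defs)
  if (anyDuplicated(nms)) stop("validation error: duplicated type names")
  if (!allow_subset) {
    missing <- setdiff(RING_TYPE_NAMES, nms)
    if (length(missing)) {
      stop("validation error: missing type(s) ",
           paste(missing, collapse = ", "),
           " (use allow_subset = TRUE for partial tables)")
    }
  }
  prios <- vapply(defs, function(d) d$priority, integer(1))
  if (anyNA(prios) || anyDuplicated(prios)) {
    stop("validation error: priorities must be unique integers")
  }
  for (d in defs) {
    if (length(d$slots) != 8L) {
      stop("validation error: type ", d$name, " must define 8 ligand slots")
    }
    for (i in seq_len(8L)) {
      s <- d$slots[[i]]
      if (!length(s$allowed) || !all(s$allowed %in% AA20)) {
        stop("validation error: type ", d$name, " slot ", i,
             ": allowed residues must be a non-empty subset of the 20-letter alphabet")
      }
      if (length(s$tolerated) && !all(s$tolerated %in% TOLERATED_UNIVERSE)) {
        stop("validation error: type ", d$name, " slot ", i,
             ": tolerated substitutions must lie in {H,D,S,T,G}")
      }
    }
    if (length(d$spacers) != 7L) {
      stop("validation error: type ", d$name, " must define 7 spacer ranges")
    }
    for (i in seq_len(7L)) {
      sp <- d$spacers[[i]]
      if (anyNA(c(sp$min, sp$max, sp$ext)) || sp$min < 0L ||
          sp$max < sp$min || sp$ext < 0L) {
        stop("validation error: type ", d$name, " spacer after ligand ", i,
             ": need 0 <= min <= max and ext >= 0")
      }
    }
    rule <- SPACER4_RULES[[d$name]]
    if (!is.null(rule)) {
      if (d$spacers[[4]]$min != rule[1] || d$spacers[[4]]$max != rule[2]) {
        stop("validation error: type ", d$name,
             " spacer after ligand 4 must be ", rule[1], "-", rule[2])
      }
    }
    spans <- core_spans(d)
    if (min(spans) < 9L || max(spans) > 16L) {
      stop("validation error: type ", d$name,
           " central-core span outside [9, 16] for some spacer combination")
    }
  }
  invisible(table)
}

# all central-core spans (ligand 3 through 6 inclusive) of one type,
# enumerated over the allowed spacer combinations, extensions excluded
core_spans <- function(def) {
  s34 <- def$spacers[[3]]$min:def$spacers[[3]]$max
  s45 <- def$spacers[[4]]$min:def$spacers[[4]]$max
  s56 <- def$spacers[[5]]$min:def$spacers[[5]]$max
  as.integer(outer(outer(s34, s45, "+"), s56, "+")) + 4L
}

#' Central-core span bounds
#'
#' Minimum and maximum span, in residues, of the central core of the RING
#' domain — ligand 3 through ligand 6 inclusive (4 ligand residues plus the
#' three intervening spacers) — enumerated over every type in the table and
#' every allowed spacer combination, extension allowances excluded. Over the
#' canonical table this is (9, 16).
#'
#' @param table A validated `ring_type_table`.
#' @return Integer vector `c(min, max)`.
#' @export
central_core_span_bounds <- function(table) {
  stopifnot(inherits(table, "ring_type_table"))
  spans <- unlist(lapply(table$defs, core_spans))
  c(min = min(spans), max = max(spans))
}

#' Query-pattern span bounds (ligand 3 through ligand 5)
#'
#' Minimum and maximum span, in residues, from ligand 3 through ligand 5
#' inclusive (3 ligand residues plus spacers 3-4 and 4-5) over every type and
#' allowed spacer combination. Over the canonical table the maximum is 13,
#' attained only by RING-v — the longest pattern needed to query the variable
#' part of the central core.
#'
#' @param table A validated `ring_type_table`.
#' @return Integer vector `c(min, max)`.
#' @export
query_pattern_span_bounds <- function(table) {
  stopifnot(inherits(table, "ring_type_table"))
  spans <- unlist(lapply(table$defs, function(d) {
    s34 <- d$spacers[[3]]$min:d$spacers[[3]]$max
    s45 <- d$spacers[[4]]$min:d$spacers[[4]]$max
    as.integer(outer(s34, s45, "+")) + 3L
  }))
  c(min = min(spans), max = max(spans))
}

#' Restrict a type table to a subset of types
#'
#' @param table A `ring_type_table`.
#' @param types Character vector of type names to keep.
#' @return A `ring_type_table` containing only the requested types.
#' @export
restrict_types <- function(table, types) {
  stopifnot(inherits(table, "ring_type_table"))
  missing <- setdiff(types, names(table$defs))
  if (length(missing)) stop("unknown type(s): ", paste(missing, collapse = ", "))
  out <- table
  out$defs <- table$defs[types]
  validate_type_table(out, allow_subset = TRUE)
}

#' Serialize a type table to YAML
#'
#' Writes the full (expanded) form: eight explicit slots and seven spacer
#' ranges per type. `load_type_table()` on the written file reproduces the
#' table exactly.
#'
#' @param table A `ring_type_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_type_table <- function(table, path) {
  stopifnot(inherits(table, "ring_type_table"))
  types <- lapply(table$defs, function(d) {
    list(
      priority = d$priority,
      slots = lapply(d$slots, function(s) {
        out <- list(allowed = as.list(s$allowed))
        if (length(s$tolerated)) out$tolerated <- as.list(s$tolerated)
        out
      }),
      spacers = lapply(d$spacers, function(sp) {
        list(min = sp$min, max = sp$max, ext = sp$ext)
      })
    )
  })
  yaml::write_yaml(list(version = table$version, types = types), path)
  invisible(path)
}

#' @export
print.ring_type_table <- function(x, ...) {
  cat("RING type table (", x$version, "): ", length(x$defs), " types\n",
      sep = "")
  for (d in x$defs) {
    cat(sprintf("  %-9s priority %d  slots 4/5: %s/%s  spacer4: %d-%d\n",
                d$name, d$priority,
                paste(d$slots[[4]]$allowed, collapse = ""),
                paste(d$slots[[5]]$allowed, collapse = ""),
                d$spacers[[4]]$min, d$spacers[[4]]$max))
  }
  invisible(x)
}

# residues satisfying a slot, split by whether they carry a deviation flag
slot_allowed <- function(def, i) def$slots[[i]]$allowed
slot_tolerated <- function(def, i) setdiff(def$slots[[i]]$tolerated,
                                           def$slots[[i]]$allowed)
slot_residues <- function(def, i, with_tolerated = TRUE) {
  if (with_tolerated) union(slot_allowed(def, i), slot_tolerated(def, i))
  else slot_allowed(def, i)
}
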