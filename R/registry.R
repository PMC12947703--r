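#' Default trait registry
#'
#' The registry records, for every trait the package knows about, its units,
#' its functional role, and the direction in which the trait is expected to
#' move under limited-water (LW) irrigation relative to ponded-water (PW)
#' controls. The direction drives the directional adjustment step of the
#' Composite Multi-Trait Index: cuticular wax, flavonols, non-photochemical
#' quenching, leaf temperature, contact angle, leaf delta13C and %N rise
#' under LW, while stomatal conductance, stomatal density, relative
#' chlorophyll, PSII quantum yields and the C:N ratio fall. %C and PhiNO
#' carry no documented expectation and are registered as neutral; neutral
#' traits are excluded from the CMTI unless re-registered.
#'
#' @return A data frame of class `trait_registry` with columns `trait`,
#'   `units`, `lw_direction` (one of `"increase"`, `"decrease"`,
#'   `"neutral"`) and `role`.
#' @seealso [register_trait()], [lw_direction()]
#' @examples
#' reg <- default_registry()
#' lw_direction(reg, "gs")
#' @export
default_registry <- function() {
  entries <- rbind(
    c("gs",            "mmol m-2 s-1",   "decrease", "stomatal"),
    c("SD",            "mm-2",           "decrease", "stomatal"),
    c("CEW",           "absorbance cm-1","increase", "surface"),
    c("flavonol",      "absorbance cm-1","increase", "surface"),
    c("RCh",           "relative units", "decrease", "photochemical"),
    c("LT",            "degC",           "increase", "other"),
    c("PhiPSII",       "dimensionless",  "decrease", "photochemical"),
    c("FvFm",          "dimensionless",  "decrease", "photochemical"),
    c("PhiNPQ",        "dimensionless",  "increase", "photochemical"),
    c("NPQt",          "dimensionless",  "increase", "photochemical"),
    c("PhiNO",         "dimensionless",  "neutral",  "photochemical"),
    c("delta13C",      "permil VPDB",    "increase", "isotope"),
    c("pctN",          "percent",        "increase", "isotope"),
    c("pctC",          "percent",        "neutral",  "isotope"),
    c("CN_ratio",      "dimensionless",  "decrease", "isotope"),
    c("contact_angle", "degrees",        "increase", "surface")
  )
  reg <- data.frame(
    trait = entries[, 1], units = entries[, 2],
    lw_direction = entries[, 3], role = entries[, 4],
    stringsAsFactors = FALSE
  )
  class(reg) <- c("trait_registry", "data.frame")
  reg
}

#' Register an additional trait or override an existing one
#'
#' @param registry A `trait_registry`.
#' @param trait Trait name token.
#' @param lw_direction Expected direction of change under LW:
#'   `"increase"`, `"decrease"` or `"neutral"`.
#' @param units Free-text units.
#' @param role Functional role label.
#' @return The updated registry.
#' @export
register_trait <- function(registry, trait, lw_direction,
                           units = "unknown", role = "other") {
  stopifnot(inherits(registry, "trait_registry"), length(trait) == 1L)
  lw_direction <- match.arg(lw_direction, c("increase", "decrease", "neutral"))
  row <- data.frame(trait = trait, units = units,
                    lw_direction = lw_direction, role = role,
                    stringsAsFactors = FALSE)
  registry <- registry[registry$trait != trait, , drop = FALSE]
  out <- rbind(as.data.frame(registry), row)
  rownames(out) <- NULL
  class(out) <- c("trait_registry", "data.frame")
  out
}

#' Look up the limited-water direction of a trait
#'
#' @inheritParams register_trait
#' @param trait Character vector of trait names.
#' @return Character vector of directions, one per trait.
#' @export
lw_direction <- function(registry, trait) {
  stopifnot(inherits(registry, "trait_registry"))
  idx <- match(trait, registry$trait)
  if (anyNA(idx)) {
    stop("trait(s) not in registry: ",
         paste(trait[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  registry$lw_direction[idx]
}

#' Read a registry override file
#'
#' The override is a YAML mapping of trait name to either a direction
#' string or a mapping with `lw_direction` and optional `units`/`role`
#' keys. Entries replace or extend the default registry.
#'
#' @param path Path to a YAML file.
#' @param base Registry to extend; defaults to [default_registry()].
#' @return A `trait_registry`.
#' @export
read_registry <- function(path, base = default_registry()) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (trait in names(cfg)) {
    entry <- cfg[[trait]]
    if (is.character(entry) && length(entry) == 1L) {
      base <- register_trait(base, trait, entry)
    } else {
      base <- register_trait(
        base, trait,
        lw_direction = entry$lw_direction,
        units = entry$units %||% "unknown",
        role = entry$role %||% "other"
      )
    }
  }
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a
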