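#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr .data
#' @importFrom stats ave rnbinom rnorm runif sd setNames
#' @importFrom utils packageVersion
NULL

KO_PATTERN <- "^K[0-9]{5}$"

PATHWAY_CATEGORIES <- c(
  "depolymerization", "sugar", "amino_acid", "lcfa_beta_oxidation",
  "scfa_oxidation", "central_carbon", "methanogenesis", "energy_conservation"
)

#' Parse a pathway step expression
#'
#' Steps are written in a flat OR-of-ANDs grammar modeled on KEGG module
#' definitions: `","` separates alternative enzymes or complexes (OR),
#' `"+"` joins the required subunits of one complex (AND), and a leading
#' `"-"` marks a subunit as optional (recorded but excluded from presence
#' and expression computations). No nesting or parentheses are allowed.
#'
#' @param text Step definition string, e.g. `"K01902+K01903,K22224"`.
#' @param step_id Short label, unique within its pathway.
#' @param key Logical; does the step count towards pathway completeness?
#' @return A `mf_step` object: a list with `step_id`, `key`, and `variants`,
#'   where each variant is a list with character vectors `required` and
#'   `optional`. Variant and subunit order follow the input text.
#' @examples
#' parse_step_expression("K01902+K01903,K22224")
#' parse_step_expression("K00248+-K99999")
#' @export
parse_step_expression <- function(text, step_id = "S1", key = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  stripped <- gsub("[[:space:]]+", "", text)
  if (!nzchar(stripped)) {
    stop("empty step expression", call. = FALSE)
  }
  variant_texts <- strsplit(stripped, ",", fixed = TRUE)[[1]]
  if (any(!nzchar(variant_texts)) || length(variant_texts) == 0L) {
    stop(sprintf("empty variant in step expression '%s'", text), call. = FALSE)
  }
  variants <- lapply(seq_along(variant_texts), function(v) {
    tokens <- strsplit(variant_texts[[v]], "+", fixed = TRUE)[[1]]
    if (any(!nzchar(tokens)) || length(tokens) == 0L) {
      stop(sprintf("empty subunit token in variant %d of '%s'", v, text),
           call. = FALSE)
    }
    optional_flag <- startsWith(tokens, "-")
    kos <- toupper(sub("^-", "", tokens))
    bad <- which(!grepl(KO_PATTERN, kos))
    if (length(bad) > 0L) {
      stop(sprintf(
        "malformed KO token '%s' (variant %d, position %d) in '%s'",
        tokens[bad[1]], v, bad[1], text
      ), call. = FALSE)
    }
    if (anyDuplicated(kos)) {
      dup <- kos[duplicated(kos)][1]
      stop(sprintf("duplicate subunit '%s' in variant %d of '%s'", dup, v, text),
           call. = FALSE)
    }
    required <- kos[!optional_flag]
    if (length(required) == 0L) {
      stop(sprintf("variant %d of '%s' has no required subunit", v, text),
           call. = FALSE)
    }
    list(required = required, optional = kos[optional_flag])
  })
  structure(
    list(step_id = as.character(step_id), key = isTRUE(key), variants = variants),
    class = "mf_step"
  )
}

#' Serialize a step back to its expression string
#'
#' Inverse of [parse_step_expression()]; preserves variant and subunit order.
#'
#' @param step A `mf_step` object.
#' @return The step definition string.
#' @export
serialize_step_expression <- function(step) {
  stopifnot(inherits(step, "mf_step"))
  paste(vapply(step$variants, function(v) {
    paste(c(v$required, paste0("-", v$optional)[seq_along(v$optional)]),
          collapse = "+")
  }, character(1)), collapse = ",")
}

# Decimal threshold -> exact integer fraction c(numerator, denominator).
# Catalog thresholds are short decimals (0.9, 1.0); up to 6 fractional
# digits are honored so the 10/11-vs-0.9 boundary never hits float noise.
threshold_fraction <- function(threshold) {
  for (d in 0:6) {
    scaled <- threshold * 10^d
    if (abs(scaled - round(scaled)) < 1e-9) {
      return(c(num = as.integer(round(scaled)), den = as.integer(10^d)))
    }
  }
  stop(sprintf("threshold %g is not a short decimal fraction", threshold),
       call. = FALSE)
}

new_pathway <- function(pathway_id, name, category, steps, threshold = 1.0) {
  if (!is.character(pathway_id) || !nzchar(pathway_id)) {
    stop("pathway_id must be a non-empty string", call. = FALSE)
  }
  if (!category %in% PATHWAY_CATEGORIES) {
    stop(sprintf("pathway '%s': unknown category '%s'", pathway_id, category),
         call. = FALSE)
  }
  if (length(steps) == 0L) {
    stop(sprintf("pathway '%s' has an empty step list", pathway_id),
         call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop(sprintf("pathway '%s': threshold %s outside (0,1]",
                 pathway_id, format(threshold)), call. = FALSE)
  }
  step_ids <- vapply(steps, `[[`, character(1), "step_id")
  if (anyDuplicated(step_ids)) {
    stop(sprintf("pathway '%s': duplicate step_id '%s'",
                 pathway_id, step_ids[duplicated(step_ids)][1]), call. = FALSE)
  }
  if (!any(vapply(steps, `[[`, logical(1), "key"))) {
    stop(sprintf("pathway '%s' has no key step", pathway_id), call. = FALSE)
  }
  structure(
    list(
      pathway_id = pathway_id, name = name, category = category,
      threshold = threshold, threshold_frac = threshold_fraction(threshold),
      steps = steps
    ),
    class = "mf_pathway"
  )
}

#' Load a pathway catalog
#'
#' Reads a YAML catalog with a top-level `pathways` list, each entry holding
#' `id`, `name`, `category`, an optional `threshold` (presence completeness
#' threshold, default 1.0 = every key step required), and `steps`: a list of
#' `{step_id, key (default true), expr}` with `expr` in the grammar of
#' [parse_step_expression()].
#'
#' @param path Path to the catalog YAML file.
#' @return A `mf_catalog` object: a named list of pathway definitions keyed
#'   by pathway id.
#' @seealso [default_catalog()] for the packaged anaerobic-carbon-flux
#'   catalog, [validate_catalog()] for the report on its structure.
#' @export
load_catalog <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$pathways) || length(raw$pathways) == 0L) {
    stop("catalog has no pathways", call. = FALSE)
  }
  pathways <- lapply(raw$pathways, function(p) {
    if (is.null(p$id)) stop("catalog entry without an id", call. = FALSE)
    steps <- lapply(p$steps, function(s) {
      parse_step_expression(
        s$expr,
        step_id = s$step_id,
        key = if (is.null(s$key)) TRUE else isTRUE(s$key)
      )
    })
    new_pathway(
      pathway_id = as.character(p$id),
      name = if (is.null(p$name)) p$id else p$name,
      category = p$category,
      steps = steps,
      threshold = if (is.null(p$threshold)) 1.0 else as.numeric(p$threshold)
    )
  })
  ids <- vapply(pathways, `[[`, character(1), "pathway_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate pathway_id '%s' in catalog",
                 ids[duplicated(ids)][1]), call. = FALSE)
  }
  structure(list(pathways = setNames(pathways, ids)), class = "mf_catalog")
}

#' Write a pathway catalog to YAML
#'
#' Serializes a catalog so that [load_catalog()] on the result reproduces it
#' field by field (round-trip identity).
#'
#' @param catalog A `mf_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "mf_catalog"))
  out <- list(pathways = lapply(unname(catalog$pathways), function(p) {
    entry <- list(id = p$pathway_id, name = p$name, category = p$category)
    if (p$threshold != 1.0) entry$threshold <- p$threshold
    entry$steps <- lapply(p$steps, function(s) {
      step <- list(step_id = s$step_id)
      if (!s$key) step$key <- FALSE
      step$expr <- serialize_step_expression(s)
      step
    })
    entry
  }))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' The packaged anaerobic carbon-flux pathway catalog
#'
#' Ninety pathways spanning polymer depolymerization, sugar and amino-acid
#' fermentation, long-chain fatty-acid beta-oxidation, syntrophic short-chain
#' fatty-acid oxidation (including the 11-step methylmalonyl-CoA route of
#' propionate degradation, the only pathway with a relaxed 0.9 completeness
#' threshold), central carbon metabolism, the four methanogenesis routes, and
#' energy-conservation modules. KO step logic is curated from KEGG
#' module/pathway maps.
#'
#' @return A `mf_catalog` with 90 pathway definitions.
#' @export
default_catalog <- function() {
  cached <- .magflux_cache$default_catalog
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "anaerobic_pathways.yaml", package = "magflux")
  if (!nzchar(path)) {
    # devtools::load_all() keeps inst/ unflattened
    path <- system.file("inst", "extdata", "anaerobic_pathways.yaml",
                        package = "magflux")
  }
  catalog <- load_catalog(path)
  .magflux_cache$default_catalog <- catalog
  catalog
}

.magflux_cache <- new.env(parent = emptyenv())

#' Validate a pathway catalog
#'
#' Report-only structural checks: KOs reused across steps of one pathway
#' (expression of such a KO is counted in every step using it), pathways
#' whose completeness threshold differs from the default 1.0 (deliberate
#' exceptions such as the methylmalonyl-CoA pathway), and pathways with no
#' key step (blocked at load time, reported here for externally built
#' objects). The catalog is never mutated.
#'
#' @param catalog A `mf_catalog`.
#' @return A tibble with columns `pathway_id`, `type`
#'   (`"duplicate_ko"`, `"threshold_exception"`, `"no_key_step"`), `detail`.
#' @export
validate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "mf_catalog"))
  rows <- list()
  for (p in catalog$pathways) {
    ko_steps <- list()
    for (s in p$steps) {
      kos <- unique(unlist(lapply(s$variants, function(v) {
        c(v$required, v$optional)
      })))
      for (ko in kos) ko_steps[[ko]] <- c(ko_steps[[ko]], s$step_id)
    }
    for (ko in names(ko_steps)) {
      if (length(ko_steps[[ko]]) > 1L) {
        rows[[length(rows) + 1L]] <- tibble(
          pathway_id = p$pathway_id, type = "duplicate_ko",
          detail = sprintf("%s in steps %s", ko,
                           paste(ko_steps[[ko]], collapse = ","))
        )
      }
    }
    if (p$threshold != 1.0) {
      rows[[length(rows) + 1L]] <- tibble(
        pathway_id = p$pathway_id, type = "threshold_exception",
        detail = sprintf("threshold %s", format(p$threshold))
      )
    }
    if (!any(vapply(p$steps, `[[`, logical(1), "key"))) {
      rows[[length(rows) + 1L]] <- tibble(
        pathway_id = p$pathway_id, type = "no_key_step", detail = ""
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble(pathway_id = character(), type = character(),
                  detail = character()))
  }
  dplyr::bind_rows(rows)
}

#' @export
print.mf_catalog <- function(x, ...) {
  cats <- table(vapply(x$pathways, `[[`, character(1), "category"))
  cat(sprintf("<mf_catalog> %d pathways\n", length(x$pathways)))
  for (nm in names(cats)) cat(sprintf("  %-20s %d\n", nm, cats[[nm]]))
  invisible(x)
}

#' @export
print.mf_pathway <- function(x, ...) {
  cat(sprintf("<mf_pathway> %s (%s), %d steps, threshold %s\n",
              x$pathway_id, x$category, length(x$steps), format(x$threshold)))
  for (s in x$steps) {
    cat(sprintf("  %-6s%s %s\n", s$step_id, if (s$key) "" else " [non-key]",
                serialize_step_expression(s)))
  }
  invisible(x)
}

# All KOs referenced by a pathway (required + optional across variants)
pathway_kos <- function(pathway, include_optional = TRUE) {
  unique(unlist(lapply(pathway$steps, function(s) {
    unlist(lapply(s$variants, function(v) {
      if (include_optional) c(v$required, v$optional) else v$required
    }))
  })))
}
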