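`%||%` <- function(a, b) if (is.null(a)) b else a

# property accessions a mode will use, given explicit params, a loaded
# table, or (for dimensional enumeration) a bare property count
.n_props <- function(params, ctx) {
  if (!is.null(params$properties)) return(length(params$properties))
  if (!is.null(ctx$ptable)) return(nrow(ctx$ptable$raw))
  ctx$n_properties %||% 0L
}

.props_or_default <- function(params, ctx, k = NULL) {
  pt <- ctx$ptable %||% chou_classic_table()
  props <- params$properties %||% {
    if (is.null(k)) rownames(pt$raw)
    else rownames(pt$raw)[seq_len(min(k, nrow(pt$raw)))]
  }
  list(ptable = pt, properties = props)
}

#' Define a descriptor mode
#'
#' A mode spec is the registry's unit: a name, parameter defaults, the
#' side inputs it needs, a dimensionality function and a compute function.
#' The registry enforces at run time that `dim(params, ctx)` equals the
#' length of every emitted descriptor.
#'
#' @param name unique mode name
#' @param dim `function(params, ctx)` returning the output dimensionality
#' @param compute `function(rec, params, ctx)` returning a
#'   [descriptor_vector()]
#' @param defaults named list of default parameter values
#' @param requires side inputs the mode needs: any of `"properties"`,
#'   `"annotations"`, `"pssm"`
#' @return a `mode_spec`
#' @export
mode_spec <- function(name, dim, compute, defaults = list(),
                      requires = character(0)) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("mode name must be a non-empty string", call. = FALSE)
  missing <- c(if (!is.function(dim)) "dim",
               if (!is.function(compute)) "compute",
               if (!is.list(defaults)) "defaults")
  if (length(missing))
    stop("mode spec for '", name, "' missing/invalid member(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(name = name, dim = dim, compute = compute,
                 defaults = defaults, requires = requires),
            class = "mode_spec")
}

#' Create an empty mode registry
#'
#' @return a `mode_registry`
#' @export
new_mode_registry <- function() {
  structure(list(env = new.env(parent = emptyenv())),
            class = "mode_registry")
}

#' Register a mode
#'
#' @param registry a [new_mode_registry()]
#' @param spec a [mode_spec()]
#' @return the registry, invisibly
#' @export
register_mode <- function(registry, spec) {
  if (!inherits(spec, "mode_spec")) {
    # accept a bare list satisfying the contract; name what is missing
    need <- c("name", "dim", "compute")
    missing <- need[!need %in% names(spec)]
    if (length(missing))
      stop("mode spec missing member(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    spec <- mode_spec(spec$name, spec$dim, spec$compute,
                      spec$defaults %||% list(),
                      spec$requires %||% character(0))
  }
  if (exists(spec$name, envir = registry$env, inherits = FALSE))
    stop("mode '", spec$name, "' already registered", call. = FALSE)
  assign(spec$name, spec, envir = registry$env)
  invisible(registry)
}

#' List registered modes
#'
#' @param registry a `mode_registry`
#' @return sorted character vector of mode names
#' @export
list_modes <- function(registry) sort(ls(registry$env))

#' Look up a mode
#'
#' @param registry a `mode_registry`
#' @param name mode name
#' @return the [mode_spec()]
#' @export
get_mode <- function(registry, name) {
  if (!exists(name, envir = registry$env, inherits = FALSE))
    stop("unknown mode '", name, "' (available: ",
         paste(list_modes(registry), collapse = ", "), ")", call. = FALSE)
  get(name, envir = registry$env, inherits = FALSE)
}

#' Compute one descriptor through the registry
#'
#' Merges defaults with `params`, runs the mode and verifies the emitted
#' length against the mode's declared dimensionality.
#'
#' @param registry a `mode_registry`
#' @param name mode name
#' @param rec a [protein_record]
#' @param params parameter overrides
#' @param ctx side-input context: a list with any of `ptable`, `go_map`,
#'   `fdom_map`, `pssm_for` (function id -> [pssm()]), `groupings`,
#'   `matrices`
#' @return a [descriptor_vector()]
#' @export
compute_descriptor <- function(registry, name, rec, params = list(),
                               ctx = list()) {
  spec <- get_mode(registry, name)
  p <- utils::modifyList(spec$defaults, params)
  out <- spec$compute(rec, p, ctx)
  expected <- spec$dim(p, ctx)
  if (length(out) != expected)
    stop("mode '", name, "' contract violation: declared dim ", expected,
         " but emitted ", length(out), " features", call. = FALSE)
  out
}

#' The built-in mode registry
#'
#' Registers the thirteen standard descriptor modes: `aac`, `dpc`, `tpc`,
#' `pseaac1`, `pseaac2`, `go`, `fdom`, `psepssm`, `nmbroto`, `moran`,
#' `geary`, `ctd`, `qso`.
#'
#' @return a populated `mode_registry`
#' @export
builtin_registry <- function() {
  reg <- new_mode_registry()

  register_mode(reg, mode_spec("aac",
    dim = function(p, ctx) 20L,
    compute = function(rec, p, ctx) aac(rec)))

  register_mode(reg, mode_spec("dpc",
    dim = function(p, ctx) 400L,
    compute = function(rec, p, ctx) dipeptide(rec)))

  register_mode(reg, mode_spec("tpc",
    dim = function(p, ctx) 8000L,
    compute = function(rec, p, ctx) tripeptide(rec)))

  register_mode(reg, mode_spec("pseaac1",
    defaults = list(lambda = 30L, w = 0.05, properties = NULL),
    requires = "properties",
    dim = function(p, ctx) 20L + p$lambda,
    compute = function(rec, p, ctx) {
      side <- .props_or_default(p, ctx, k = 3L)
      type1_pseaac(rec, lambda = p$lambda, w = p$w,
                   ptable = side$ptable, properties = side$properties)
    }))

  register_mode(reg, mode_spec("pseaac2",
    defaults = list(lambda = 30L, w = 0.05, properties = NULL),
    requires = "properties",
    dim = function(p, ctx) 20L + 2L * p$lambda,
    compute = function(rec, p, ctx) {
      side <- .props_or_default(p, ctx, k = 2L)
      type2_pseaac(rec, lambda = p$lambda, w = p$w,
                   ptable = side$ptable, properties = side$properties)
    }))

  register_mode(reg, mode_spec("go",
    requires = "annotations",
    dim = function(p, ctx) length((ctx$go_map %||% list(universe = NULL))$universe) %||% 0L,
    compute = function(rec, p, ctx) {
      if (is.null(ctx$go_map))
        stop("mode 'go' needs an annotation map (ctx$go_map)", call. = FALSE)
      binary_vector(rec$id, ctx$go_map, mode = "go")
    }))

  register_mode(reg, mode_spec("fdom",
    requires = "annotations",
    dim = function(p, ctx) length((ctx$fdom_map %||% list(universe = NULL))$universe) %||% 0L,
    compute = function(rec, p, ctx) {
      if (is.null(ctx$fdom_map))
        stop("mode 'fdom' needs an annotation map (ctx$fdom_map)", call. = FALSE)
      binary_vector(rec$id, ctx$fdom_map, mode = "fdom")
    }))

  register_mode(reg, mode_spec("psepssm",
    defaults = list(xi = 10L),
    requires = "pssm",
    dim = function(p, ctx) 20L + 20L * p$xi,
    compute = function(rec, p, ctx) {
      if (is.null(ctx$pssm_for))
        stop("mode 'psepssm' needs a PSSM source (ctx$pssm_for)", call. = FALSE)
      m <- ctx$pssm_for(rec$id)
      if (nrow(m$scores) != rec$length)
        stop("PSSM for '", rec$id, "' has ", nrow(m$scores),
             " rows but the sequence has L = ", rec$length, call. = FALSE)
      psepssm(normalize_pssm(m), xi = p$xi)
    }))

  for (fam in c("nmbroto", "moran", "geary")) {
    local({
      family <- fam
      register_mode(reg, mode_spec(family,
        defaults = list(max_lag = 30L, properties = NULL),
        requires = "properties",
        dim = function(p, ctx) .n_props(p, ctx) * p$max_lag,
        compute = function(rec, p, ctx) {
          side <- .props_or_default(p, ctx)
          autocorr_vector(rec, side$ptable, side$properties,
                          max_lag = p$max_lag, family = family)
        }))
    })
  }

  register_mode(reg, mode_spec("ctd",
    defaults = list(groupings = NULL),
    dim = function(p, ctx)
      21L * length(p$groupings %||% ctx$groupings %||% vector("list", 7L)),
    compute = function(rec, p, ctx)
      ctd_vector(rec, p$groupings %||% ctx$groupings %||% ctd_groupings())))

  register_mode(reg, mode_spec("qso",
    defaults = list(max_lag = 30L, w = 0.1, matrices = NULL),
    dim = function(p, ctx)
      (20L + p$max_lag) *
        length(p$matrices %||% ctx$matrices %||% vector("list", 2L)),
    compute = function(rec, p, ctx) {
      mats <- p$matrices %||% ctx$matrices %||% qso_matrices()
      parts <- lapply(unname(mats), function(dm)
        qso_vector(rec, dm, max_lag = p$max_lag, w = p$w))
      vals <- unlist(lapply(parts, function(v)
        stats::setNames(as.numeric(v), names(v))))
      descriptor_vector("qso", vals)
    }))

  reg
}

#' Register a plugin mode from a file
#'
#' The user-defined-mode mechanism: an R file whose last evaluated
#' expression is a [mode_spec()] (or a bare list with `name`, `dim`,
#' `compute` members). The file is sourced in an isolated environment; a
#' broken plugin raises an error and leaves the registry untouched.
#' Plugins may not shadow built-in or previously registered names.
#'
#' @param registry a `mode_registry`
#' @param path path to the plugin R file
#' @return the registry, invisibly
#' @export
register_plugin <- function(registry, path) {
  env <- new.env(parent = asNamespace("pseaacg"))
  spec <- tryCatch(source(path, local = env)$value,
                   error = function(e)
                     stop("plugin '", path, "' failed to load: ",
                          conditionMessage(e), call. = FALSE))
  register_mode(registry, spec)
}
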