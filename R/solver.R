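# Uniform LP/MILP solver interface.
#
# All linear and mixed-integer programs in the package go through hs_solve(),
# which drives the HiGHS solver shipped inside scipy (scipy.optimize.milp)
# via reticulate.  HiGHS is deterministic in single-threaded use, which keeps
# every FBA solve and MILP run reproducible.

.scipy_opt <- function() {
  if (is.null(.adaptuc$scipy_opt)) {
    if (!reticulate::py_available(initialize = TRUE)) {
      stop("No python interpreter available for the HiGHS solver backend; ",
           "set RETICULATE_PYTHON to a python with scipy installed.",
           call. = FALSE)
    }
    .adaptuc$scipy_opt <- reticulate::import("scipy.optimize", convert = TRUE)
    # importing scipy.sparse up front makes reticulate convert dgCMatrix
    # objects to scipy sparse matrices automatically
    .adaptuc$scipy_sparse <- reticulate::import("scipy.sparse", convert = TRUE)
    # scipy warns that HiGHS-specific tolerance options are passed verbatim;
    # that is exactly what we want
    wrn <- reticulate::import("warnings", convert = TRUE)
    wrn$filterwarnings("ignore", message = "Unrecognized options")
  }
  .adaptuc$scipy_opt
}

.hs_status <- function(code) {
  switch(as.character(code),
         "0" = "optimal",
         "1" = "limit",
         "2" = "infeasible",
         "3" = "unbounded",
         "error")
}

#' Solve a linear or mixed-integer linear program
#'
#' Minimal uniform interface over the HiGHS solver: minimise or maximise
#' `obj %*% x` subject to `row_lb <= A %*% x <= row_ub` and
#' `lb <= x <= ub`, with optional integrality restrictions.
#'
#' @param obj numeric objective coefficient vector.
#' @param A constraint matrix (`Matrix::dgCMatrix` or base matrix); may have
#'   zero rows.
#' @param row_lb,row_ub numeric constraint bounds (`-Inf`/`Inf` allowed).
#' @param lb,ub numeric variable bounds.
#' @param integrality integer vector (0 = continuous, 1 = integer) or `NULL`
#'   for a pure LP.
#' @param maximize logical; maximise instead of minimise.
#' @param time_limit seconds, or `NULL` for no limit.
#' @param mip_rel_gap relative MIP gap (ignored for LPs).
#'
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"limit"`, `"error"`), `objective`, solution vector `x` (or `NULL`) and
#'   the raw solver `message`.
#' @keywords internal
hs_solve <- function(obj, A, row_lb, row_ub, lb, ub,
                     integrality = NULL, maximize = FALSE,
                     time_limit = NULL, mip_rel_gap = 1e-4) {
  sp <- .scipy_opt()
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  cvec <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  constraints <- list()
  if (!is.null(A) && nrow(A) > 0L) {
    A <- methods::as(methods::as(methods::as(A, "dMatrix"), "generalMatrix"),
                     "CsparseMatrix")
    constraints <- list(sp$LinearConstraint(reticulate::r_to_py(A),
                                            lb = as.numeric(row_lb),
                                            ub = as.numeric(row_ub)))
  }
  intg <- if (is.null(integrality)) rep(0, n) else as.numeric(integrality)
  # strict HiGHS tolerances: big-M envelopes in the design MILP must not be
  # eroded by loose integrality (the extra names pass through to HiGHS)
  opts <- list(mip_rel_gap = mip_rel_gap,
               primal_feasibility_tolerance = 1e-9,
               dual_feasibility_tolerance = 1e-9,
               mip_feasibility_tolerance = 1e-9)
  if (!is.null(time_limit)) opts$time_limit <- as.numeric(time_limit)

  res <- tryCatch(
    sp$milp(c = cvec,
            constraints = constraints,
            integrality = intg,
            bounds = sp$Bounds(as.numeric(lb), as.numeric(ub)),
            options = opts),
    error = function(e) NULL)
  if (is.null(res)) {
    return(list(status = "error", objective = NA_real_, x = NULL,
                message = "solver call failed"))
  }
  status <- .hs_status(res$status)
  x <- tryCatch(as.numeric(res$x), error = function(e) NULL)
  if (length(x) == 0L) x <- NULL
  objective <- if (!is.null(res$fun) && length(res$fun) == 1L && !is.null(x)) {
    if (maximize) -as.numeric(res$fun) else as.numeric(res$fun)
  } else NA_real_
  # HiGHS sometimes reports "limit" with an incumbent; keep it
  list(status = status, objective = objective, x = x,
       message = as.character(res$message))
}

# Sparse triplet accumulator used by the FBA and MILP builders.  Rows are
# appended with arbitrary bounds; build() returns a dgCMatrix plus bounds.
.lp_builder <- function(n_var) {
  env <- new.env(parent = emptyenv())
  env$i <- integer(0); env$j <- integer(0); env$x <- numeric(0)
  env$rlb <- numeric(0); env$rub <- numeric(0)
  env$nrow <- 0L; env$nvar <- n_var
  env$add_row <- function(cols, vals, lb, ub) {
    keep <- vals != 0
    env$nrow <- env$nrow + 1L
    env$i <- c(env$i, rep.int(env$nrow, sum(keep)))
    env$j <- c(env$j, cols[keep])
    env$x <- c(env$x, vals[keep])
    env$rlb <- c(env$rlb, lb)
    env$rub <- c(env$rub, ub)
    invisible(env$nrow)
  }
  env$add_matrix <- function(M, row_offset_cols, lb, ub) {
    # append all rows of sparse matrix M whose columns map to variable
    # indices row_offset_cols (a vector of length ncol(M))
    T <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
    env$i <- c(env$i, env$nrow + T@i + 1L)
    env$j <- c(env$j, row_offset_cols[T@j + 1L])
    env$x <- c(env$x, T@x)
    env$rlb <- c(env$rlb, lb)
    env$rub <- c(env$rub, ub)
    env$nrow <- env$nrow + nrow(M)
    invisible(env$nrow)
  }
  env$build <- function() {
    A <- Matrix::sparseMatrix(i = env$i, j = env$j, x = env$x,
                              dims = c(env$nrow, env$nvar))
    list(A = A, row_lb = env$rlb, row_ub = env$rub)
  }
  env
}
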