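#' Final refinement by iteratively retaining informative variables (IRIV)
#'
#' Stage-3 backward refinement. Each round draws a random binary inclusion
#' matrix (`n_submodels` rows, inclusion probability `inclusion_prob`), fits
#' a PLSR sub-model per row and scores it by 10-fold RMSE_CV. For every
#' channel `i` the difference of means
#' `DM_i = mean(RMSE_CV | i included) - mean(RMSE_CV | i excluded)` is
#' computed together with a Mann-Whitney U test between the two RMSE_CV
#' populations. Channels are classified by `DM_i` and the p-value at
#' `alpha`: `DM_i < 0` marks strong (p < alpha) or weak (p >= alpha)
#' informative channels, `DM_i >= 0` marks interfering (p < alpha) or
#' uninformative (p >= alpha) ones. Uninformative and interfering channels
#' are dropped and the round repeats until none remain; a final backward
#' elimination then removes weak channels one-by-one whenever removal lowers
#' RMSE_CV.
#'
#' @inheritParams irf_select
#' @param n_submodels Binary-matrix rows per round.
#' @param inclusion_prob Inclusion probability per entry.
#' @param alpha Mann-Whitney significance threshold.
#' @param n_rounds Safety cap on elimination rounds.
#' @return List with `result` (a [selection_result()], stage `"optimal"`)
#'   and `assessments` (one data frame per round with columns `channel`,
#'   `dm`, `p_value`, `class`).
#' @export
iriv_select <- function(X, y, n_submodels = 500, inclusion_prob = 0.5,
                        alpha = 0.05, max_components = 10, n_rounds = 10,
                        folds = 10, seed = 1, channels = NULL) {
  X <- as_X(X); y <- as_y(y)
  check_selector_input(X, y, min_p = 2L)
  p <- ncol(X); n <- nrow(X)
  channels <- as.integer(channels %||% seq_len(p))

  res <- with_seed(seed, {
    fold <- cv_folds(n, folds, seed)
    current <- seq_len(p)
    assessments <- list()
    last_class <- NULL
    for (r in seq_len(n_rounds)) {
      pc <- length(current)
      if (pc < 2L) break
      min_row <- if (pc <= 2L) 1L else 2L
      M <- matrix(runif(n_submodels * pc) < inclusion_prob, n_submodels, pc)
      short <- which(rowSums(M) < min_row)
      for (m in short) M[m, sample.int(pc, min_row)] <- TRUE
      # every channel needs both populations represented
      allin <- which(colSums(M) == n_submodels)
      for (j in allin) M[sample.int(n_submodels, 1L), j] <- FALSE
      noin <- which(colSums(M) == 0)
      for (j in noin) M[sample.int(n_submodels, 1L), j] <- TRUE
      errs <- vapply(seq_len(n_submodels), function(m)
        rmsecv(X, y, current[M[m, ]], fold, max_components), 0)
      dm <- p_val <- numeric(pc)
      for (j in seq_len(pc)) {
        e_in <- errs[M[, j]]; e_out <- errs[!M[, j]]
        dm[j] <- mean(e_in) - mean(e_out)
        p_val[j] <- suppressWarnings(
          wilcox.test(e_in, e_out, exact = FALSE)$p.value)
      }
      cls <- ifelse(dm < 0, ifelse(p_val < alpha, "strong", "weak"),
                    ifelse(p_val < alpha, "interfering", "uninformative"))
      assessments[[r]] <- data.frame(channel = channels[current], dm = dm,
                                     p_value = p_val, class = cls)
      keep <- which(dm < 0)
      if (length(keep) < 1L) {          # degenerate: nothing informative
        current <- current[which.min(dm)]
        last_class <- "weak"
        break
      }
      if (length(keep) == length(current)) {
        last_class <- cls
        break
      }
      last_class <- cls[keep]
      current <- current[keep]
    }
    # backward elimination of weak channels
    err <- rmsecv(X, y, current, fold, max_components)
    if (!is.null(last_class) && length(last_class) == length(current)) {
      weak <- current[last_class == "weak"]
      a <- assessments[[length(assessments)]]
      weak <- weak[order(-a$dm[match(channels[weak], a$channel)])]
      for (ch in weak) {
        if (length(current) <= 1L) break
        rest <- setdiff(current, ch)
        e2 <- rmsecv(X, y, rest, fold, max_components)
        if (e2 < err) { current <- rest; err <- e2 }
      }
    }
    list(sel = current, err = err, assessments = assessments)
  })
  result <- selection_result(to_window(res$sel, channels), "optimal", "IRIV",
                             seed = seed, best_rmsecv = res$err)
  list(result = result, assessments = res$assessments)
}

#' Final refinement by a genetic algorithm
#'
#' Stage-3 subset search with binary-encoded chromosomes capped at
#' `max_vars` set bits (over-full chromosomes are repaired by clearing
#' random bits). Fitness is the negative 10-fold RMSE_CV of the encoded
#' subset; evolution uses tournament selection (size 2), single-point
#' crossover with probability `p_crossover`, per-bit mutation with
#' probability `p_mutation`, and elitism (the best chromosome always
#' survives, so best-so-far fitness is non-decreasing). The search stops
#' once `n_evaluations` distinct subsets have been evaluated and returns the
#' best-ever chromosome's channels.
#'
#' @inheritParams irf_select
#' @param n_chromosomes Population size.
#' @param max_vars Upper limit on set bits per chromosome.
#' @param p_crossover Crossover probability.
#' @param p_mutation Per-bit mutation probability.
#' @param n_evaluations Budget of subset evaluations.
#' @return A [selection_result()] with stage `"optimal"`; its trace records
#'   the evaluated subset sizes and the best fitness per generation.
#' @export
ga_select <- function(X, y, n_chromosomes = 30, max_vars = 30,
                      p_crossover = 0.5, p_mutation = 0.01,
                      n_evaluations = 200, max_components = 10,
                      folds = 10, seed = 1, channels = NULL) {
  X <- as_X(X); y <- as_y(y)
  check_selector_input(X, y, min_p = 2L)
  p <- ncol(X); n <- nrow(X)
  channels <- as.integer(channels %||% seq_len(p))

  res <- with_seed(seed, {
    fold <- cv_folds(n, folds, seed)
    repair <- function(bits) {
      k <- sum(bits)
      if (k == 0L) bits[sample.int(p, 1L)] <- TRUE
      else if (k > max_vars)
        bits[sample(which(bits), k - max_vars)] <- FALSE
      bits
    }
    cache <- new.env(parent = emptyenv())
    n_eval <- 0L
    sizes <- integer(0)
    fitness <- function(bits) {
      key <- paste(which(bits), collapse = ",")
      if (!is.null(cache[[key]])) return(cache[[key]])
      n_eval <<- n_eval + 1L
      sizes <<- c(sizes, sum(bits))
      val <- -rmsecv(X, y, which(bits), fold, max_components)
      cache[[key]] <- val
      val
    }
    pop <- lapply(seq_len(n_chromosomes), function(i)
      repair(runif(p) < min(0.5, max_vars / (2 * p))))
    fit <- vapply(pop, fitness, 0)
    best <- list(bits = pop[[which.max(fit)]], fit = max(fit))
    gen_best <- best$fit
    stagnant <- 0L
    while (n_eval < n_evaluations && stagnant < 20L) {
      n_eval_before <- n_eval
      newpop <- list(best$bits)  # elitism
      while (length(newpop) < n_chromosomes) {
        pick <- function() {
          c2 <- sample.int(n_chromosomes, 2L)
          pop[[c2[which.max(fit[c2])]]]
        }
        a <- pick(); b <- pick()
        if (runif(1) < p_crossover && p > 1) {
          cut <- sample.int(p - 1L, 1L)
          child <- c(a[seq_len(cut)], b[(cut + 1L):p])
        } else child <- a
        flip <- runif(p) < p_mutation
        child[flip] <- !child[flip]
        newpop[[length(newpop) + 1L]] <- repair(child)
      }
      pop <- newpop
      fit <- vapply(pop, fitness, 0)
      if (max(fit) > best$fit)
        best <- list(bits = pop[[which.max(fit)]], fit = max(fit))
      gen_best <- c(gen_best, best$fit)
      stagnant <- if (n_eval == n_eval_before) stagnant + 1L else 0L
    }
    list(sel = which(best$bits), err = -best$fit, sizes = sizes,
         gen_best = gen_best)
  })
  out <- selection_result(to_window(res$sel, channels), "optimal", "GA",
                          trace = data.frame(generation = seq_along(res$gen_best),
                                             best_fitness = res$gen_best),
                          seed = seed, best_rmsecv = res$err)
  out$evaluated_sizes <- res$sizes
  out
}
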