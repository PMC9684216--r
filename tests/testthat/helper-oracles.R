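# Shared fixtures and independent oracles used across the test files.

# small network for fast simulation-based tests (properties do not depend on
# the map size)
fast_params <- function(...) {
  args <- list(grid_rows = 8L, grid_cols = 8L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(vt_params, args)
}

# miniature network for the fixed-point oracle
mini_params <- function(...) {
  args <- list(grid_rows = 3L, grid_cols = 3L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(vt_params, args)
}

# Independent steady-state oracle: solves the fixed-point equations
# u = net(sigmoid(u)) of the full two-hemisphere network directly with a
# general-purpose root finder (no Euler integration, no delay line --- the
# delay is irrelevant at a steady state).  State layout: for each hemisphere
# (bright, dim): u_t (n), u_v (n), u_m, u_i.
fixed_point_oracle <- function(drives, matrices, params, u_start = NULL) {
  n <- matrices$n_units
  su <- params$sigmoid_slope_unisensory;  tu <- params$sigmoid_thresh_unisensory
  sm <- params$sigmoid_slope_multisensory; tm <- params$sigmoid_thresh_multisensory
  si <- params$sigmoid_slope_inhibitory;  ti <- params$sigmoid_thresh_inhibitory
  unpack <- function(u) {
    list(t_b = u[1:n], v_b = u[n + 1:n], m_b = u[2 * n + 1], i_b = u[2 * n + 2],
         t_d = u[2 * n + 2 + 1:n], v_d = u[3 * n + 2 + 1:n],
         m_d = u[4 * n + 3], i_d = u[4 * n + 4])
  }
  net <- function(u) {
    s <- unpack(u)
    y_t_b <- 1 / (1 + exp(-su * (s$t_b - tu)))
    y_v_b <- 1 / (1 + exp(-su * (s$v_b - tu)))
    y_t_d <- 1 / (1 + exp(-su * (s$t_d - tu)))
    y_v_d <- 1 / (1 + exp(-su * (s$v_d - tu)))
    y_m_b <- 1 / (1 + exp(-sm * (s$m_b - tm)))
    y_m_d <- 1 / (1 + exp(-sm * (s$m_d - tm)))
    y_i_b <- 1 / (1 + exp(-si * (s$i_b - ti)))
    y_i_d <- 1 / (1 + exp(-si * (s$i_d - ti)))
    b <- matrices$bright; d <- matrices$dim
    c(drives$t_bright + as.vector(b$K_t %*% y_t_b) + b$fb_t * y_m_b - b$inh_t * y_i_b,
      drives$v_bright + as.vector(b$K_v %*% y_v_b) + b$fb_v * y_m_b - b$inh_v * y_i_b,
      sum(b$ff_t * y_t_b) + sum(b$ff_v * y_v_b),
      d$w_inter * y_m_d,
      drives$t_dim + as.vector(d$K_t %*% y_t_d) + d$fb_t * y_m_d - d$inh_t * y_i_d,
      drives$v_dim + as.vector(d$K_v %*% y_v_d) + d$fb_v * y_m_d - d$inh_v * y_i_d,
      sum(d$ff_t * y_t_d) + sum(d$ff_v * y_v_d),
      b$w_inter * y_m_b)
  }
  if (is.null(u_start))
    u_start <- c(drives$t_bright, drives$v_bright, 0, 0,
                 drives$t_dim, drives$v_dim, 0, 0)
  sol <- pracma::fsolve(function(u) u - net(u), u_start, tol = 1e-12)
  s <- unpack(sol$x)
  list(y_t_b = 1 / (1 + exp(-su * (s$t_b - tu))),
       y_v_b = 1 / (1 + exp(-su * (s$v_b - tu))),
       y_m_b = 1 / (1 + exp(-sm * (s$m_b - tm))),
       y_i_b = 1 / (1 + exp(-si * (s$i_b - ti))),
       y_t_d = 1 / (1 + exp(-su * (s$t_d - tu))),
       y_v_d = 1 / (1 + exp(-su * (s$v_d - tu))),
       y_m_d = 1 / (1 + exp(-sm * (s$m_d - tm))),
       y_i_d = 1 / (1 + exp(-si * (s$i_d - ti))))
}

# Independent spreadsheet-style oracle for the corrected rates and LBI,
# written directly from the definitions on plain data frames.
lbi_oracle <- function(vt_tab, bl_tab) {
  cell <- function(tab, tc, vc, col)
    tab[tab$tactile == tc & tab$visual == vc, col]
  sapply(unique(vt_tab$visual), function(vc) {
    b <- (cell(vt_tab, "B", vc, "p_bright_only") +
            cell(vt_tab, "BD", vc, "p_bright_only") +
            cell(vt_tab, "N", vc, "p_bright_only")) -
      (cell(bl_tab, "B", "none", "p_bright_only") +
         cell(bl_tab, "BD", "none", "p_bright_only") +
         cell(bl_tab, "N", "none", "p_bright_only"))
    d <- (cell(vt_tab, "D", vc, "p_dim_only") +
            cell(vt_tab, "BD", vc, "p_dim_only") +
            cell(vt_tab, "N", vc, "p_dim_only")) -
      (cell(bl_tab, "D", "none", "p_dim_only") +
         cell(bl_tab, "BD", "none", "p_dim_only") +
         cell(bl_tab, "N", "none", "p_dim_only"))
    b - d
  })
}

# random response table over a given block's condition set
random_response_table <- function(block = "VT") {
  conds <- trial_conditions(block)
  props <- t(apply(matrix(stats::rgamma(nrow(conds) * 4, shape = 1), ncol = 4),
                   1, function(g) g / sum(g)))
  out <- cbind(conds, as.data.frame(props))
  names(out)[3:6] <- c("p_bright_only", "p_dim_only", "p_both", "p_none")
  out
}

# swap the bright/dim labelling of a response table (hands relabelled)
swap_hands_table <- function(tab) {
  out <- tab
  out$tactile <- c(B = "D", D = "B", BD = "BD", N = "N")[tab$tactile]
  out$visual <- c(none = "none", both = "both",
                  brightLED = "dimLED", dimLED = "brightLED")[tab$visual]
  tmp <- out$p_bright_only
  out$p_bright_only <- out$p_dim_only
  out$p_dim_only <- tmp
  out
}

# synthetic one-hemisphere steady state for perception unit tests
synthetic_hemi <- function(peak_t, y_m, n = 4) {
  y_t <- rep(0.01, n); y_t[1] <- peak_t
  list(y_t = y_t, y_v = rep(0, n), y_m = y_m, y_i = 0)
}
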