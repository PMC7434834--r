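// Compiled core of the S-CTRNNPB: teacher-forced and closed-loop forward
// passes, full-batch backpropagation through time for the heteroscedastic
// Gaussian negative log-likelihood, the momentum training loop, and the
// sliding-window parametric-bias adaptation used during real-time
// interaction.  All randomness lives on the R side; every function here is
// deterministic in its arguments.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// Internal state of the variance neurons is clamped to +-UV_CAP before
// exponentiation so v = exp(u) cannot overflow.  The clamp is numerical
// overflow protection only: gradients are computed from the clamped v as if
// the clamp were the identity (straight-through), so a transiently saturated
// variance neuron still feels the restoring force toward the data variance.
static const double UV_CAP = 20.0;

namespace {

struct Net {
  mat Wxc, Wcc, Wpc, Wcm, Wcv;
  vec bc, bm, bv, invtau, leak;
  uword nc, ni, np, no;
};

Net net_from_list(const List& p) {
  Net n;
  n.Wxc = Rcpp::as<mat>(p["W_xc"]);
  n.Wcc = Rcpp::as<mat>(p["W_cc"]);
  n.Wpc = Rcpp::as<mat>(p["W_pc"]);
  n.Wcm = Rcpp::as<mat>(p["W_cm"]);
  n.Wcv = Rcpp::as<mat>(p["W_cv"]);
  n.bc = Rcpp::as<vec>(p["b_c"]);
  n.bm = Rcpp::as<vec>(p["b_m"]);
  n.bv = Rcpp::as<vec>(p["b_v"]);
  vec tau = Rcpp::as<vec>(p["tau"]);
  n.invtau = 1.0 / tau;
  n.leak = 1.0 - n.invtau;
  n.nc = n.Wcc.n_rows;
  n.ni = n.Wxc.n_cols;
  n.np = n.Wpc.n_cols;
  n.no = n.Wcm.n_rows;
  return n;
}

List net_to_list(const Net& n, const List& proto) {
  List out = clone(proto);
  out["W_xc"] = n.Wxc;
  out["W_cc"] = n.Wcc;
  out["W_pc"] = n.Wpc;
  out["W_cm"] = n.Wcm;
  out["W_cv"] = n.Wcv;
  out["b_m"] = n.bm;
  out["b_v"] = n.bv;
  // b_c and tau are untouched by training and copied through from proto.
  return out;
}

struct Grads {
  mat gWxc, gWcc, gWpc, gWcm, gWcv;
  vec gbm, gbv;
  mat gU0;  // np x S

  void init(const Net& n, uword S) {
    gWxc.zeros(n.nc, n.ni);
    gWcc.zeros(n.nc, n.nc);
    gWpc.zeros(n.nc, n.np);
    gWcm.zeros(n.no, n.nc);
    gWcv.zeros(n.no, n.nc);
    gbm.zeros(n.no);
    gbv.zeros(n.no);
    gU0.zeros(n.np, S);
  }
};

// Workspace for the batched forward/backward pass over S equally long
// sequences.  Allocated once and reused across epochs.
struct Workspace {
  cube C, Y, V, E;  // C: nc x S x Tm;  Y,V,E: no x S x Tm
  mat P;                  // np x S
  uword Tm, S;

  void init(const Net& n, uword Tm_, uword S_) {
    Tm = Tm_;
    S = S_;
    C.set_size(n.nc, S, Tm);
    Y.set_size(n.no, S, Tm);
    V.set_size(n.no, S, Tm);
    E.set_size(n.no, S, Tm);
    P.set_size(n.np, S);
  }
};

// Teacher-forced forward over the batch; fills ws and returns the summed
// negative log-likelihood (the unaveraged total over sequences, steps and
// output dimensions).  X is T x D x S; inputs are rows 1..T-1, targets rows
// 2..T; context internal states start at zero.
double batch_forward(const Net& n, const cube& X, const mat& U0pb,
                     Workspace& ws) {
  const uword Tm = X.n_rows - 1, S = X.n_slices;
  ws.P = tanh(U0pb);
  mat U(n.nc, S, fill::zeros), Cprev(n.nc, S, fill::zeros);
  mat Xt(n.ni, S), Tg(n.no, S);
  double loss = 0.0;
  const double cst = std::log(2.0 * datum::pi);
  for (uword t = 0; t < Tm; ++t) {
    for (uword s = 0; s < S; ++s) {
      Xt.col(s) = X.slice(s).row(t).t();
      Tg.col(s) = X.slice(s).row(t + 1).t();
    }
    mat A = n.Wxc * Xt + n.Wcc * Cprev + n.Wpc * ws.P;
    A.each_col() += n.bc;
    A.each_col() %= n.invtau;
    U = A + U.each_col() % n.leak;
    mat C = tanh(U);
    mat Um = n.Wcm * C;
    Um.each_col() += n.bm;
    mat Uv = n.Wcv * C;
    Uv.each_col() += n.bv;
    Uv = clamp(Uv, -UV_CAP, UV_CAP);
    mat Yt = tanh(Um), Vt = exp(Uv);
    mat Et = Tg - Yt;
    loss += accu(0.5 * (cst + log(Vt)) + square(Et) / (2.0 * Vt));
    ws.C.slice(t) = C;
    ws.Y.slice(t) = Yt;
    ws.V.slice(t) = Vt;
    ws.E.slice(t) = Et;
    Cprev = C;
  }
  return loss;
}

// BPTT through the teacher-forced pass.  Gradients cover all synaptic
// weights, the mean/variance biases and the per-sequence initial PB internal
// states; context biases are excluded from the update path by construction.
void batch_backward(const Net& n, const cube& X, Workspace& ws, Grads& g) {
  const uword Tm = ws.Tm, S = ws.S;
  g.init(n, S);
  mat delta_next(n.nc, S, fill::zeros);
  mat gP(n.np, S, fill::zeros);
  mat Xt(n.ni, S);
  for (uword t = Tm; t-- > 0;) {
    const mat& C = ws.C.slice(t);
    const mat& Yt = ws.Y.slice(t);
    const mat& Vt = ws.V.slice(t);
    const mat& Et = ws.E.slice(t);
    mat Gm = (-Et / Vt) % (1.0 - square(Yt));
    mat Gv = 0.5 * (1.0 - square(Et) / Vt);
    g.gWcm += Gm * C.t();
    g.gWcv += Gv * C.t();
    g.gbm += sum(Gm, 1);
    g.gbv += sum(Gv, 1);
    mat dC = n.Wcm.t() * Gm + n.Wcv.t() * Gv;
    if (t + 1 < Tm) {
      // delta_next already holds d L / d u_{t+1}
      dC += n.Wcc.t() * (delta_next.each_col() % n.invtau);
    }
    mat delta = (1.0 - square(C)) % dC;
    if (t + 1 < Tm) delta += delta_next.each_col() % n.leak;
    mat Dt = delta.each_col() % n.invtau;
    for (uword s = 0; s < S; ++s) Xt.col(s) = X.slice(s).row(t).t();
    g.gWxc += Dt * Xt.t();
    if (t > 0) g.gWcc += Dt * ws.C.slice(t - 1).t();
    // at t = 0 the previous context output is zero, so no W_cc term
    g.gWpc += Dt * ws.P.t();
    gP += n.Wpc.t() * Dt;
    delta_next = delta;
  }
  g.gU0 = (1.0 - square(ws.P)) % gP;
}

}  // namespace

// [[Rcpp::export]]
List cpp_grads(List params, arma::mat u0pb, arma::cube X) {
  Net n = net_from_list(params);
  Workspace ws;
  ws.init(n, X.n_rows - 1, X.n_slices);
  double loss = batch_forward(n, X, u0pb, ws);
  Grads g;
  batch_backward(n, X, ws, g);
  return List::create(
      Named("loss") = loss, Named("W_xc") = g.gWxc, Named("W_cc") = g.gWcc,
      Named("W_pc") = g.gWpc, Named("W_cm") = g.gWcm, Named("W_cv") = g.gWcv,
      Named("b_m") = g.gbm, Named("b_v") = g.gbv, Named("u0_pb") = g.gU0);
}

// [[Rcpp::export]]
List cpp_train(List params, arma::mat u0pb, arma::cube X, int n_epochs,
               double alpha, double eta, int thin) {
  Net n = net_from_list(params);
  const uword S = X.n_slices;
  Workspace ws;
  ws.init(n, X.n_rows - 1, S);
  Grads g, vel;
  vel.init(n, S);
  std::vector<double> trace;
  std::vector<int> trace_epoch;
  double loss = NA_REAL;
  for (int ep = 0; ep < n_epochs; ++ep) {
    loss = batch_forward(n, X, u0pb, ws);
    if (!std::isfinite(loss))
      Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep);
    if (ep % thin == 0) {
      trace.push_back(loss);
      trace_epoch.push_back(ep);
    }
    batch_backward(n, X, ws, g);
    // Momentum gradient descent; velocity starts at zero.
    vel.gWxc = -alpha * g.gWxc + eta * vel.gWxc;  n.Wxc += vel.gWxc;
    vel.gWcc = -alpha * g.gWcc + eta * vel.gWcc;  n.Wcc += vel.gWcc;
    vel.gWpc = -alpha * g.gWpc + eta * vel.gWpc;  n.Wpc += vel.gWpc;
    vel.gWcm = -alpha * g.gWcm + eta * vel.gWcm;  n.Wcm += vel.gWcm;
    vel.gWcv = -alpha * g.gWcv + eta * vel.gWcv;  n.Wcv += vel.gWcv;
    vel.gbm = -alpha * g.gbm + eta * vel.gbm;     n.bm += vel.gbm;
    vel.gbv = -alpha * g.gbv + eta * vel.gbv;     n.bv += vel.gbv;
    vel.gU0 = -alpha * g.gU0 + eta * vel.gU0;     u0pb += vel.gU0;
    if (ep % 1000 == 0) Rcpp::checkUserInterrupt();
  }
  double final_loss = batch_forward(n, X, u0pb, ws);
  trace.push_back(final_loss);
  trace_epoch.push_back(n_epochs);
  return List::create(Named("params") = net_to_list(n, params),
                      Named("u0_pb") = u0pb,
                      Named("loss") = trace,
                      Named("epoch") = trace_epoch,
                      Named("final_loss") = final_loss);
}

// [[Rcpp::export]]
List cpp_open_loop(List params, arma::vec u_pb, arma::mat X) {
  Net n = net_from_list(params);
  const uword T = X.n_rows, Tm = T - 1;
  vec p = tanh(u_pb);
  vec u(n.nc, fill::zeros), c(n.nc, fill::zeros);
  mat Y(Tm, n.no), V(Tm, n.no), C(Tm, n.nc), U(Tm, n.nc), L(Tm, n.no);
  const double cst = std::log(2.0 * datum::pi);
  for (uword t = 0; t < Tm; ++t) {
    vec x = X.row(t).t();
    u = n.invtau % (n.Wxc * x + n.Wcc * c + n.Wpc * p + n.bc) + n.leak % u;
    c = tanh(u);
    vec y = tanh(n.Wcm * c + n.bm);
    vec v = exp(clamp(n.Wcv * c + n.bv, -UV_CAP, UV_CAP));
    vec tgt = X.row(t + 1).t();
    vec e = tgt - y;
    L.row(t) = (0.5 * (cst + log(v)) + square(e) / (2.0 * v)).t();
    Y.row(t) = y.t();
    V.row(t) = v.t();
    C.row(t) = c.t();
    U.row(t) = u.t();
  }
  return List::create(Named("y") = Y, Named("v") = V, Named("context") = C,
                      Named("u_context") = U, Named("loss") = L,
                      Named("p") = p);
}

// [[Rcpp::export]]
List cpp_closed_loop(List params, arma::vec u_pb, arma::vec x0, int n_steps,
                     arma::vec u_init) {
  Net n = net_from_list(params);
  vec p = tanh(u_pb);
  vec u = u_init, c = tanh(u_init), x = x0;
  mat Y(n_steps, n.no), V(n_steps, n.no), C(n_steps, n.nc), U(n_steps, n.nc);
  for (int t = 0; t < n_steps; ++t) {
    u = n.invtau % (n.Wxc * x + n.Wcc * c + n.Wpc * p + n.bc) + n.leak % u;
    c = tanh(u);
    vec y = tanh(n.Wcm * c + n.bm);
    vec v = exp(clamp(n.Wcv * c + n.bv, -UV_CAP, UV_CAP));
    Y.row(t) = y.t();
    V.row(t) = v.t();
    C.row(t) = c.t();
    U.row(t) = u.t();
    x = y;  // own mean prediction becomes the next input
  }
  return List::create(Named("y") = Y, Named("v") = V, Named("context") = C,
                      Named("u_context") = U, Named("p") = p);
}

// Closed-loop regeneration of one W-step window plus BPTT to the PB internal
// state.  obs holds the observed input vectors at window steps 2..W (full
// dimension; `dims` selects which output dimensions enter the loss, 0-based).
// Returns the loss of the window under the given PB (before any update when
// iters = 0) together with the updated PB state, momentum velocity and the
// final-step prediction (the network's forecast for the step after the
// window).
// [[Rcpp::export]]
List cpp_pb_adapt(List params, arma::vec u_pb, arma::vec vel,
                  arma::vec u_anchor, arma::vec x1, arma::mat obs,
                  arma::uvec dims, int iters, double alpha, double eta) {
  Net n = net_from_list(params);
  const uword W = obs.n_rows + 1;
  const double cst = std::log(2.0 * datum::pi);
  mat U(n.nc, W), C(n.nc, W), Y(n.no, W), V(n.no, W), E(n.no, W);
  double loss = NA_REAL;

  auto fwd = [&](const vec& upb) {
    vec p = tanh(upb);
    vec u = u_anchor, c = tanh(u_anchor), x = x1;
    double l = 0.0;
    for (uword j = 0; j < W; ++j) {
      u = n.invtau % (n.Wxc * x + n.Wcc * c + n.Wpc * p + n.bc) + n.leak % u;
      c = tanh(u);
      vec um = n.Wcm * c + n.bm;
      vec uv = n.Wcv * c + n.bv;
      uv = clamp(uv, -UV_CAP, UV_CAP);
      vec y = tanh(um), v = exp(uv);
      U.col(j) = u; C.col(j) = c; Y.col(j) = y; V.col(j) = v;
      E.col(j).zeros();
      if (j + 1 < W) {
        // prediction at window step j+1 is scored against the observation
        // that arrived at window step j+2 (one-step-ahead alignment)
        for (uword d : dims) {
          double e = obs(j, d) - y(d);
          E(d, j) = e;
          l += 0.5 * (cst + std::log(v(d))) + e * e / (2.0 * v(d));
        }
      }
      x = y;
    }
    return l;
  };

  auto grad_upb = [&](const vec& upb) {
    vec p = tanh(upb);
    vec delta_next(n.nc, fill::zeros), gp(n.np, fill::zeros);
    for (uword j = W; j-- > 0;) {
      vec dY(n.no, fill::zeros), Gv(n.no, fill::zeros);
      if (j + 1 < W) {
        // feedback path: y_j was the input of step j+1
        dY += n.Wxc.t() * (n.invtau % delta_next);
        for (uword d : dims) {
          double e = E(d, j), v = V(d, j);
          dY(d) += -e / v;
          Gv(d) = 0.5 * (1.0 - e * e / v);
        }
      }
      vec Gm = dY % (1.0 - square(Y.col(j)));
      vec dC = n.Wcm.t() * Gm + n.Wcv.t() * Gv;
      if (j + 1 < W) dC += n.Wcc.t() * (n.invtau % delta_next);
      vec delta = (1.0 - square(C.col(j))) % dC;
      if (j + 1 < W) delta += n.leak % delta_next;
      gp += n.Wpc.t() * (n.invtau % delta);
      delta_next = delta;
    }
    return vec((1.0 - square(p)) % gp);
  };

  for (int it = 0; it < iters; ++it) {
    fwd(u_pb);
    vec g = grad_upb(u_pb);
    vel = -alpha * g + eta * vel;
    u_pb += vel;
    if (!u_pb.is_finite()) Rcpp::stop("PB adaptation diverged");
  }
  loss = fwd(u_pb);
  return List::create(Named("u_pb") = u_pb, Named("velocity") = vel,
                      Named("loss") = loss,
                      Named("y_next") = vec(Y.col(W - 1)),
                      Named("v_next") = vec(V.col(W - 1)));
}
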