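// Bytecode evaluator for kinetic-law expressions plus the adaptive-step
// integrators (linearly-implicit Rosenbrock for stiff systems, embedded
// Dormand-Prince RK45 for non-stiff ones).  Opcode numbers must match
// .OPC in R/math.R.  Tableaus and controller constants are supplied from
// the R side so that the exported single-step helpers share them.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>

using namespace Rcpp;

enum Op {
  OP_CONST = 1, OP_VAR = 2, OP_TIME = 3,
  OP_ADD = 4, OP_SUB = 5, OP_MUL = 6, OP_DIV = 7, OP_POW = 8, OP_NEG = 9,
  OP_EXP = 10, OP_LN = 11, OP_LOG10 = 12, OP_SQRT = 13, OP_ABS = 14,
  OP_FLOOR = 15, OP_CEIL = 16,
  OP_SIN = 17, OP_COS = 18, OP_TAN = 19, OP_ASIN = 20, OP_ACOS = 21,
  OP_ATAN = 22, OP_SINH = 23, OP_COSH = 24, OP_TANH = 25,
  OP_MIN = 26, OP_MAX = 27,
  OP_GT = 28, OP_GEQ = 29, OP_LT = 30, OP_LEQ = 31, OP_EQ = 32, OP_NEQ = 33,
  OP_AND = 34, OP_OR = 35, OP_NOT = 36, OP_XOR = 37, OP_SELECT = 38
};

struct Prog {
  std::vector<int> op;
  std::vector<int> arg;     // 1-based symbol slot for OP_VAR
  std::vector<double> num;  // constant for OP_CONST
  int depth;
};

static Prog prog_from_list(const List& pl) {
  Prog p;
  IntegerVector op = pl["op"], arg = pl["arg"];
  NumericVector num = pl["num"];
  p.op.assign(op.begin(), op.end());
  p.arg.assign(arg.begin(), arg.end());
  p.num.assign(num.begin(), num.end());
  p.depth = as<int>(pl["depth"]);
  return p;
}

static double run_prog(const Prog& p, const double* vals, double t,
                       double* stack) {
  int sp = -1;
  const size_t n = p.op.size();
  for (size_t i = 0; i < n; ++i) {
    switch (p.op[i]) {
    case OP_CONST: stack[++sp] = p.num[i]; break;
    case OP_VAR:   stack[++sp] = vals[p.arg[i] - 1]; break;
    case OP_TIME:  stack[++sp] = t; break;
    case OP_ADD: --sp; stack[sp] += stack[sp + 1]; break;
    case OP_SUB: --sp; stack[sp] -= stack[sp + 1]; break;
    case OP_MUL: --sp; stack[sp] *= stack[sp + 1]; break;
    case OP_DIV: --sp; stack[sp] /= stack[sp + 1]; break;
    case OP_POW: --sp; stack[sp] = std::pow(stack[sp], stack[sp + 1]); break;
    case OP_NEG: stack[sp] = -stack[sp]; break;
    case OP_EXP: stack[sp] = std::exp(stack[sp]); break;
    case OP_LN: stack[sp] = std::log(stack[sp]); break;
    case OP_LOG10: stack[sp] = std::log10(stack[sp]); break;
    case OP_SQRT: stack[sp] = std::sqrt(stack[sp]); break;
    case OP_ABS: stack[sp] = std::fabs(stack[sp]); break;
    case OP_FLOOR: stack[sp] = std::floor(stack[sp]); break;
    case OP_CEIL: stack[sp] = std::ceil(stack[sp]); break;
    case OP_SIN: stack[sp] = std::sin(stack[sp]); break;
    case OP_COS: stack[sp] = std::cos(stack[sp]); break;
    case OP_TAN: stack[sp] = std::tan(stack[sp]); break;
    case OP_ASIN: stack[sp] = std::asin(stack[sp]); break;
    case OP_ACOS: stack[sp] = std::acos(stack[sp]); break;
    case OP_ATAN: stack[sp] = std::atan(stack[sp]); break;
    case OP_SINH: stack[sp] = std::sinh(stack[sp]); break;
    case OP_COSH: stack[sp] = std::cosh(stack[sp]); break;
    case OP_TANH: stack[sp] = std::tanh(stack[sp]); break;
    case OP_MIN: --sp;
      stack[sp] = stack[sp] < stack[sp + 1] ? stack[sp] : stack[sp + 1];
      break;
    case OP_MAX: --sp;
      stack[sp] = stack[sp] > stack[sp + 1] ? stack[sp] : stack[sp + 1];
      break;
    case OP_GT: --sp; stack[sp] = stack[sp] > stack[sp + 1]; break;
    case OP_GEQ: --sp; stack[sp] = stack[sp] >= stack[sp + 1]; break;
    case OP_LT: --sp; stack[sp] = stack[sp] < stack[sp + 1]; break;
    case OP_LEQ: --sp; stack[sp] = stack[sp] <= stack[sp + 1]; break;
    case OP_EQ: --sp; stack[sp] = stack[sp] == stack[sp + 1]; break;
    case OP_NEQ: --sp; stack[sp] = stack[sp] != stack[sp + 1]; break;
    case OP_AND: --sp;
      stack[sp] = (stack[sp] != 0) && (stack[sp + 1] != 0); break;
    case OP_OR: --sp;
      stack[sp] = (stack[sp] != 0) || (stack[sp + 1] != 0); break;
    case OP_NOT: stack[sp] = stack[sp] == 0; break;
    case OP_XOR: --sp;
      stack[sp] = ((stack[sp] != 0) + (stack[sp + 1] != 0)) == 1; break;
    case OP_SELECT: { // stack: cond, val, rest
      sp -= 2;
      stack[sp] = (stack[sp] != 0) ? stack[sp + 1] : stack[sp + 2];
      break;
    }
    default: stop("bad opcode");
    }
  }
  return stack[0];
}

// ---------------------------------------------------------------------------

struct EventC {
  Prog trigger;
  bool init_value;
  std::vector<int> target;      // 1-based symbol slot
  std::vector<int> state_pos;   // 1-based state position or 0
  std::vector<double> conv;     // amount = conv * value for species targets
  std::vector<Prog> prog;
};

struct EvalSys {
  int nsym = 0;
  int nstate = 0;
  int nrxn = 0;
  std::vector<double> tmpl;         // baseline symbol values
  std::vector<int> state_sym;       // 1-based
  std::vector<double> state_conv;   // context value = y / conv
  std::vector<double> N;            // col-major nstate x nrxn
  std::vector<Prog> rates;
  std::vector<int> asg_target;      // 1-based
  std::vector<Prog> asg_prog;
  std::vector<int> rr_pos;          // 1-based state position
  std::vector<double> rr_conv;
  std::vector<Prog> rr_prog;
  std::vector<EventC> events;
  std::vector<int> out_sym;         // 1-based symbol slots reported
  int max_depth = 1;
};

// [[Rcpp::export]]
SEXP cpp_build_sys(List spec) {
  EvalSys* s = new EvalSys();
  s->nsym = as<int>(spec["nsym"]);
  NumericVector tmpl = spec["template"];
  s->tmpl.assign(tmpl.begin(), tmpl.end());
  IntegerVector ss = spec["state_sym"];
  s->state_sym.assign(ss.begin(), ss.end());
  NumericVector sc = spec["state_conv"];
  s->state_conv.assign(sc.begin(), sc.end());
  s->nstate = (int)s->state_sym.size();
  NumericMatrix N = spec["N"];
  s->nrxn = N.ncol();
  s->N.assign(N.begin(), N.end());
  List rates = spec["rates"];
  for (int j = 0; j < rates.size(); ++j)
    s->rates.push_back(prog_from_list(rates[j]));
  List asg = spec["assignments"];
  for (int j = 0; j < asg.size(); ++j) {
    List a = asg[j];
    s->asg_target.push_back(as<int>(a["target"]));
    s->asg_prog.push_back(prog_from_list(a["prog"]));
  }
  List rr = spec["rate_rules"];
  for (int j = 0; j < rr.size(); ++j) {
    List a = rr[j];
    s->rr_pos.push_back(as<int>(a["pos"]));
    s->rr_conv.push_back(as<double>(a["conv"]));
    s->rr_prog.push_back(prog_from_list(a["prog"]));
  }
  List ev = spec["events"];
  for (int j = 0; j < ev.size(); ++j) {
    List e = ev[j];
    EventC ec;
    ec.trigger = prog_from_list(e["trigger"]);
    ec.init_value = as<bool>(e["init_value"]);
    List asgs = e["assignments"];
    for (int k = 0; k < asgs.size(); ++k) {
      List a = asgs[k];
      ec.target.push_back(as<int>(a["target"]));
      ec.state_pos.push_back(as<int>(a["state_pos"]));
      ec.conv.push_back(as<double>(a["conv"]));
      ec.prog.push_back(prog_from_list(a["prog"]));
    }
    s->events.push_back(ec);
  }
  IntegerVector os = spec["out_sym"];
  s->out_sym.assign(os.begin(), os.end());
  int md = 1;
  for (auto& p : s->rates) md = std::max(md, p.depth);
  for (auto& p : s->asg_prog) md = std::max(md, p.depth);
  for (auto& p : s->rr_prog) md = std::max(md, p.depth);
  for (auto& e : s->events) {
    md = std::max(md, e.trigger.depth);
    for (auto& p : e.prog) md = std::max(md, p.depth);
  }
  s->max_depth = md;
  XPtr<EvalSys> ptr(s, true);
  return ptr;
}

// [[Rcpp::export]]
bool cpp_ptr_valid(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != nullptr;
}

// [[Rcpp::export]]
double cpp_eval_prog(List prog, NumericVector vals, double t) {
  Prog p = prog_from_list(prog);
  std::vector<double> stack(p.depth + 4);
  return run_prog(p, vals.begin(), t, stack.data());
}

// ---------------------------------------------------------------------------
// derivative functor: compiled system or R function

struct Deriv {
  EvalSys* sys = nullptr;
  Function* rf = nullptr;
  const double* cur_tmpl = nullptr; // overrides + event updates applied
  int n = 0;                        // state dimension (unaugmented)
  std::vector<double> vals, v, stack;
  long n_eval = 0;
  int bad_rxn = 0;                  // 1-based index of non-finite rate

  void init(int n_) {
    n = n_;
    if (sys) {
      vals.resize(sys->nsym);
      v.resize(sys->nrxn);
      stack.resize(sys->max_depth + 4);
    }
  }

  void build_context(double t, const double* y) {
    std::memcpy(vals.data(), cur_tmpl, sys->nsym * sizeof(double));
    for (int i = 0; i < sys->nstate; ++i)
      vals[sys->state_sym[i] - 1] = y[i] / sys->state_conv[i];
    for (size_t k = 0; k < sys->asg_prog.size(); ++k)
      vals[sys->asg_target[k] - 1] =
        run_prog(sys->asg_prog[k], vals.data(), t, stack.data());
  }

  // returns false on non-finite rate
  bool operator()(double t, const double* y, double* dy) {
    ++n_eval;
    if (sys) {
      build_context(t, y);
      for (int j = 0; j < sys->nrxn; ++j) {
        v[j] = run_prog(sys->rates[j], vals.data(), t, stack.data());
        if (!std::isfinite(v[j])) { bad_rxn = j + 1; return false; }
      }
      for (int i = 0; i < sys->nstate; ++i) dy[i] = 0.0;
      const double* N = sys->N.data();
      for (int j = 0; j < sys->nrxn; ++j) {
        const double vj = v[j];
        if (vj == 0.0) continue;
        const double* col = N + (size_t)j * sys->nstate;
        for (int i = 0; i < sys->nstate; ++i) dy[i] += col[i] * vj;
      }
      for (size_t k = 0; k < sys->rr_prog.size(); ++k)
        dy[sys->rr_pos[k] - 1] += sys->rr_conv[k] *
          run_prog(sys->rr_prog[k], vals.data(), t, stack.data());
      return true;
    }
    NumericVector yv(n);
    std::memcpy(yv.begin(), y, n * sizeof(double));
    NumericVector r = (*rf)(t, yv);
    if ((int)r.size() != n) stop("derivative function returned wrong length");
    bool ok = true;
    for (int i = 0; i < n; ++i) {
      dy[i] = r[i];
      if (!std::isfinite(dy[i])) ok = false;
    }
    return ok;
  }

  double eval_trigger(const Prog& p, double t, const double* y) {
    build_context(t, y);
    return run_prog(p, vals.data(), t, stack.data());
  }
};

// [[Rcpp::export]]
List cpp_derivs(SEXP sysptr, double t, NumericVector y,
                IntegerVector ov_idx, NumericVector ov_val) {
  XPtr<EvalSys> sp(sysptr);
  EvalSys* sys = sp.get();
  std::vector<double> tmpl = sys->tmpl;
  for (int k = 0; k < ov_idx.size(); ++k) tmpl[ov_idx[k] - 1] = ov_val[k];
  Deriv d;
  d.sys = sys; d.cur_tmpl = tmpl.data();
  d.init(sys->nstate);
  NumericVector dy(sys->nstate);
  bool ok = d(t, y.begin(), dy.begin());
  return List::create(_["dy"] = dy, _["ok"] = ok, _["bad_rxn"] = d.bad_rxn);
}

// ---------------------------------------------------------------------------
// dense LU with partial pivoting (tiny systems)

static bool lu_decomp(std::vector<double>& A, std::vector<int>& piv, int n) {
  for (int i = 0; i < n; ++i) piv[i] = i;
  for (int k = 0; k < n; ++k) {
    int p = k; double mx = std::fabs(A[k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double a = std::fabs(A[i * n + k]);
      if (a > mx) { mx = a; p = i; }
    }
    if (mx == 0.0 || !std::isfinite(mx)) return false;
    if (p != k) {
      for (int j = 0; j < n; ++j) std::swap(A[k * n + j], A[p * n + j]);
      std::swap(piv[k], piv[p]);
    }
    const double akk = A[k * n + k];
    for (int i = k + 1; i < n; ++i) {
      A[i * n + k] /= akk;
      const double lik = A[i * n + k];
      for (int j = k + 1; j < n; ++j) A[i * n + j] -= lik * A[k * n + j];
    }
  }
  return true;
}

static void lu_solve(const std::vector<double>& A,
                     const std::vector<int>& piv, int n,
                     const double* b, double* x) {
  std::vector<double> y(n);
  for (int i = 0; i < n; ++i) y[i] = b[piv[i]];
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < i; ++j) y[i] -= A[i * n + j] * y[j];
  for (int i = n - 1; i >= 0; --i) {
    for (int j = i + 1; j < n; ++j) y[i] -= A[i * n + j] * y[j];
    y[i] /= A[i * n + i];
  }
  for (int i = 0; i < n; ++i) x[i] = y[i];
}

// forward-difference Jacobian on the augmented state (time appended)
static bool num_jac_aug(Deriv& f, double t, const double* yaug, int n1,
                        const double* f0, std::vector<double>& J) {
  const double sqeps = 1.4901161193847656e-08;
  std::vector<double> yp(yaug, yaug + n1), f1(n1);
  const int n = n1 - 1;
  for (int i = 0; i < n1; ++i) {
    const double yi = yp[i];
    double h = sqeps * std::fabs(yi);
    if (h < sqeps) h = sqeps;
    yp[i] = yi + h;
    const double tt = yp[n];
    if (!f(tt, yp.data(), f1.data())) return false;
    f1[n] = 1.0;
    for (int r = 0; r < n1; ++r) J[r * n1 + i] = (f1[r] - f0[r]) / h;
    yp[i] = yi;
  }
  return true;
}

// ---------------------------------------------------------------------------

struct RosTab {
  double gamma;
  std::vector<double> A, C, b, e; // A,C row-major s x s
  int s;
  int order;
};

static RosTab ros_from_list(const List& tl) {
  RosTab t;
  t.gamma = as<double>(tl["gamma"]);
  NumericMatrix A = tl["A"], C = tl["C"];
  t.s = A.nrow();
  t.A.resize(t.s * t.s); t.C.resize(t.s * t.s);
  for (int i = 0; i < t.s; ++i)
    for (int j = 0; j < t.s; ++j) {
      t.A[i * t.s + j] = A(i, j);
      t.C[i * t.s + j] = C(i, j);
    }
  NumericVector b = tl["b"], e = tl["e"];
  t.b.assign(b.begin(), b.end());
  t.e.assign(e.begin(), e.end());
  t.order = as<int>(tl["order"]);
  return t;
}

// One Rosenbrock step on the augmented system (time as extra component).
// Returns false if the stage matrix is singular or f went non-finite.
static bool ros_step(Deriv& f, const RosTab& T, double t, double h,
                     const std::vector<double>& yaug,
                     const std::vector<double>& f0,
                     std::vector<double>& ynew, std::vector<double>& err) {
  const int n1 = (int)yaug.size();
  const int n = n1 - 1;
  const int s = T.s;
  std::vector<double> J(n1 * n1);
  if (!num_jac_aug(f, t, yaug.data(), n1, f0.data(), J)) return false;
  std::vector<double> W(n1 * n1);
  const double d = 1.0 / (T.gamma * h);
  for (int i = 0; i < n1 * n1; ++i) W[i] = -J[i];
  for (int i = 0; i < n1; ++i) W[i * n1 + i] += d;
  std::vector<int> piv(n1);
  if (!lu_decomp(W, piv, n1)) return false;

  std::vector<std::vector<double>> g(s, std::vector<double>(n1));
  std::vector<double> ys(n1), fe(n1), rhs(n1);
  for (int i = 0; i < s; ++i) {
    for (int r = 0; r < n1; ++r) ys[r] = yaug[r];
    for (int j = 0; j < i; ++j) {
      const double a = T.A[i * s + j];
      if (a != 0.0)
        for (int r = 0; r < n1; ++r) ys[r] += a * g[j][r];
    }
    if (i == 0) {
      for (int r = 0; r < n1; ++r) fe[r] = f0[r];
    } else {
      if (!f(ys[n], ys.data(), fe.data())) return false;
      fe[n] = 1.0;
    }
    for (int r = 0; r < n1; ++r) rhs[r] = fe[r];
    for (int j = 0; j < i; ++j) {
      const double c = T.C[i * s + j];
      if (c != 0.0)
        for (int r = 0; r < n1; ++r) rhs[r] += (c / h) * g[j][r];
    }
    lu_solve(W, piv, n1, rhs.data(), g[i].data());
  }
  for (int r = 0; r < n1; ++r) { ynew[r] = yaug[r]; err[r] = 0.0; }
  for (int i = 0; i < s; ++i) {
    for (int r = 0; r < n1; ++r) {
      ynew[r] += T.b[i] * g[i][r];
      err[r] += T.e[i] * g[i][r];
    }
  }
  for (int r = 0; r < n; ++r) if (!std::isfinite(ynew[r])) return false;
  return true;
}

// [[Rcpp::export]]
List cpp_ros_step(SEXP sysptr, Function rfun, bool use_fun, double t,
                  NumericVector y, double h, List tableau,
                  IntegerVector ov_idx, NumericVector ov_val) {
  RosTab T = ros_from_list(tableau);
  Deriv f;
  std::vector<double> tmpl;
  if (use_fun) {
    f.rf = &rfun;
    f.init(y.size());
  } else {
    EvalSys* sys = (EvalSys*)R_ExternalPtrAddr(sysptr);
    if (!sys) stop("stale system pointer");
    tmpl = sys->tmpl;
    for (int k = 0; k < ov_idx.size(); ++k) tmpl[ov_idx[k] - 1] = ov_val[k];
    f.sys = sys; f.cur_tmpl = tmpl.data();
    f.init(sys->nstate);
  }
  const int n = y.size(), n1 = n + 1;
  std::vector<double> yaug(n1), f0(n1), ynew(n1), err(n1);
  for (int i = 0; i < n; ++i) yaug[i] = y[i];
  yaug[n] = t;
  if (!f(t, yaug.data(), f0.data()))
    return List::create(_["ok"] = false);
  f0[n] = 1.0;
  bool ok = ros_step(f, T, t, h, yaug, f0, ynew, err);
  NumericVector yn(n), ee(n);
  for (int i = 0; i < n; ++i) { yn[i] = ynew[i]; ee[i] = err[i]; }
  return List::create(_["ok"] = ok, _["y_new"] = yn, _["err"] = ee);
}

// ---------------------------------------------------------------------------

struct RKTab {
  std::vector<double> A, b, bs, c;
  int s, order;
  bool fsal;
};

static RKTab rk_from_list(const List& tl) {
  RKTab t;
  NumericMatrix A = tl["A"];
  t.s = A.nrow();
  t.A.resize(t.s * t.s);
  for (int i = 0; i < t.s; ++i)
    for (int j = 0; j < t.s; ++j) t.A[i * t.s + j] = A(i, j);
  NumericVector b = tl["b"], bs = tl["bs"], c = tl["c"];
  t.b.assign(b.begin(), b.end());
  t.bs.assign(bs.begin(), bs.end());
  t.c.assign(c.begin(), c.end());
  t.order = as<int>(tl["order"]);
  t.fsal = as<bool>(tl["fsal"]);
  return t;
}

static bool rk_step(Deriv& f, const RKTab& T, double t, double h,
                    const std::vector<double>& y,
                    const std::vector<double>& f0,
                    std::vector<double>& ynew, std::vector<double>& err,
                    std::vector<double>& flast) {
  const int n = (int)y.size();
  const int s = T.s;
  std::vector<std::vector<double>> k(s, std::vector<double>(n));
  std::vector<double> ys(n);
  k[0] = f0;
  for (int i = 1; i < s; ++i) {
    for (int r = 0; r < n; ++r) ys[r] = y[r];
    for (int j = 0; j < i; ++j) {
      const double a = T.A[i * s + j];
      if (a != 0.0)
        for (int r = 0; r < n; ++r) ys[r] += h * a * k[j][r];
    }
    if (!f(t + T.c[i] * h, ys.data(), k[i].data())) return false;
  }
  for (int r = 0; r < n; ++r) { ynew[r] = y[r]; err[r] = 0.0; }
  for (int i = 0; i < s; ++i) {
    const double bi = T.b[i], di = T.b[i] - T.bs[i];
    if (bi != 0.0)
      for (int r = 0; r < n; ++r) ynew[r] += h * bi * k[i][r];
    if (di != 0.0)
      for (int r = 0; r < n; ++r) err[r] += h * di * k[i][r];
  }
  for (int r = 0; r < n; ++r) if (!std::isfinite(ynew[r])) return false;
  flast = k[s - 1]; // FSAL stage evaluated at (t+h, ynew) for DOPRI
  return true;
}

// ---------------------------------------------------------------------------

static double err_norm(const double* err, const double* y0, const double* y1,
                       int n, double atol, double rtol) {
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double sc = atol + rtol * std::max(std::fabs(y0[i]), std::fabs(y1[i]));
    double e = err[i] / sc;
    acc += e * e;
  }
  return std::sqrt(acc / n);
}

static void hermite(double th, double h, const double* y0, const double* f0,
                    const double* y1, const double* f1, int n, double* out) {
  const double t2 = th * th, t3 = t2 * th;
  const double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + th;
  const double h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
  for (int i = 0; i < n; ++i)
    out[i] = h00 * y0[i] + h10 * h * f0[i] + h01 * y1[i] + h11 * h * f1[i];
}

// Full adaptive integration.  Returns trajectory values at out_times for
// the symbols listed in out_sym (compiled mode) or the raw state (function
// mode).  status: 0 ok, 1 step-size underflow / non-finite, 2 max steps.
// [[Rcpp::export]]
List cpp_integrate(SEXP sysptr, Function rfun, bool use_fun,
                   NumericVector y0, double t0, double t1,
                   NumericVector out_times, double atol, double rtol,
                   double h0, double hmax, int max_steps,
                   List ros_tab, List rk_tab, int method,
                   IntegerVector ov_idx, NumericVector ov_val) {
  Deriv f;
  std::vector<double> tmpl;
  EvalSys* sys = nullptr;
  if (use_fun) {
    f.rf = &rfun;
    f.init(y0.size());
  } else {
    sys = (EvalSys*)R_ExternalPtrAddr(sysptr);
    if (!sys) stop("stale system pointer");
    tmpl = sys->tmpl;
    for (int k = 0; k < ov_idx.size(); ++k) tmpl[ov_idx[k] - 1] = ov_val[k];
    f.sys = sys; f.cur_tmpl = tmpl.data();
    f.init(sys->nstate);
  }
  const int n = y0.size();
  const bool ros = (method == 1);
  RosTab RT; RKTab KT;
  int order;
  if (ros) { RT = ros_from_list(ros_tab); order = RT.order; }
  else { KT = rk_from_list(rk_tab); order = KT.order; }

  const int n_out = out_times.size();
  const int n_cols = use_fun ? n : (int)sys->out_sym.size();
  NumericMatrix out(n_out, n_cols);
  std::fill(out.begin(), out.end(), NA_REAL);

  // working state: augmented for rosenbrock
  const int nw = ros ? n + 1 : n;
  std::vector<double> y(nw), f0(nw), ynew(nw), err(nw), fnew(nw), yi(nw);
  for (int i = 0; i < n; ++i) y[i] = y0[i];
  if (ros) y[n] = t0;

  double t = t0;
  double span = t1 - t0;
  double h = (h0 > 0) ? h0 : span / 100.0;
  if (hmax > 0 && h > hmax) h = hmax;
  const double hmin = 1e-14 * span;
  int steps = 0, status = 0;
  double t_fail = NA_REAL;
  long n_accept = 0;

  // event trigger states
  std::vector<char> trig;
  if (!use_fun && !sys->events.empty()) {
    trig.resize(sys->events.size());
    for (size_t e = 0; e < sys->events.size(); ++e)
      trig[e] = sys->events[e].init_value ? 1 : 0;
  }

  auto fill_row = [&](int row, double tt, const double* yy) {
    if (use_fun) {
      for (int c = 0; c < n_cols; ++c) out(row, c) = yy[c];
    } else {
      f.build_context(tt, yy);
      for (int c = 0; c < n_cols; ++c)
        out(row, c) = f.vals[sys->out_sym[c] - 1];
    }
  };

  // fire event at (tt, yy in/out); applies assignments, updates template
  auto apply_event = [&](const EventC& ev, double tt, double* yy) {
    std::vector<double> vals_new(ev.prog.size());
    f.build_context(tt, yy);
    std::vector<double> ctx = f.vals; // values at trigger time
    for (size_t k = 0; k < ev.prog.size(); ++k)
      vals_new[k] = run_prog(ev.prog[k], ctx.data(), tt, f.stack.data());
    for (size_t k = 0; k < ev.prog.size(); ++k) {
      if (ev.state_pos[k] > 0)
        yy[ev.state_pos[k] - 1] = vals_new[k] * ev.conv[k];
      else
        tmpl[ev.target[k] - 1] = vals_new[k];
    }
  };

  // events possibly true at the initial time
  if (!trig.empty()) {
    for (size_t e = 0; e < sys->events.size(); ++e) {
      double cur = f.eval_trigger(sys->events[e].trigger, t, y.data());
      if (!trig[e] && cur != 0) {
        apply_event(sys->events[e], t, y.data());
        trig[e] = 1;
      } else {
        trig[e] = cur != 0;
      }
    }
  }

  int out_idx = 0;
  const double teps = 1e-12 * (std::fabs(t0) + std::fabs(t1) + 1.0);
  while (out_idx < n_out && out_times[out_idx] <= t0 + teps) {
    fill_row(out_idx, t0, y.data());
    ++out_idx;
  }

  bool have_f0 = false;
  while (t < t1 - teps) {
    if (steps++ >= max_steps) { status = 2; t_fail = t; break; }
    if (t + h > t1) h = t1 - t;
    if (!have_f0) {
      if (!f(t, y.data(), f0.data())) { status = 1; t_fail = t; break; }
      if (ros) f0[n] = 1.0;
      have_f0 = true;
    }
    bool ok;
    if (ros) ok = ros_step(f, RT, t, h, y, f0, ynew, err);
    else ok = rk_step(f, KT, t, h, y, f0, ynew, err, fnew);
    double enorm = ok ? err_norm(err.data(), y.data(), ynew.data(), n,
                                 atol, rtol)
                      : 1e10;
    if (ok && enorm <= 1.0) {
      // end-point derivative for dense output / FSAL
      if (ros) {
        if (!f(t + h, ynew.data(), fnew.data())) {
          status = 1; t_fail = t; break;
        }
        fnew[n] = 1.0;
      } else if (!KT.fsal) {
        if (!f(t + h, ynew.data(), fnew.data())) {
          status = 1; t_fail = t; break;
        }
      }
      double t_acc = t + h;
      double* y_acc = ynew.data();

      // event localisation on (t, t+h]
      if (!trig.empty()) {
        std::vector<int> flipped;
        for (size_t e = 0; e < sys->events.size(); ++e) {
          double cur = f.eval_trigger(sys->events[e].trigger, t_acc, y_acc);
          if (!trig[e] && cur != 0) flipped.push_back((int)e);
        }
        if (!flipped.empty()) {
          double lo = t, hi = t_acc;
          const double btol = 1e-9 * (t_acc - t);
          while (hi - lo > btol) {
            double mid = 0.5 * (lo + hi);
            hermite((mid - t) / h, h, y.data(), f0.data(), ynew.data(),
                    fnew.data(), n, yi.data());
            if (ros) yi[n] = mid;
            bool any = false;
            for (int e : flipped) {
              if (!trig[e] &&
                  f.eval_trigger(sys->events[e].trigger, mid, yi.data()) != 0) {
                any = true; break;
              }
            }
            if (any) hi = mid; else lo = mid;
          }
          double tstar = hi;
          hermite((tstar - t) / h, h, y.data(), f0.data(), ynew.data(),
                  fnew.data(), n, yi.data());
          if (ros) yi[n] = tstar;
          // output rows before the event
          while (out_idx < n_out && out_times[out_idx] <= tstar + teps) {
            double to = out_times[out_idx];
            std::vector<double> yo(nw);
            hermite((to - t) / h, h, y.data(), f0.data(), ynew.data(),
                    fnew.data(), n, yo.data());
            fill_row(out_idx, to, yo.data());
            ++out_idx;
          }
          // fire, in document order, every event whose trigger is true now
          for (size_t e = 0; e < sys->events.size(); ++e) {
            double cur = f.eval_trigger(sys->events[e].trigger, tstar,
                                        yi.data());
            if (!trig[e] && cur != 0) {
              apply_event(sys->events[e], tstar, yi.data());
              trig[e] = 1;
            }
          }
          for (size_t e = 0; e < sys->events.size(); ++e)
            trig[e] = f.eval_trigger(sys->events[e].trigger, tstar,
                                     yi.data()) != 0;
          t = tstar;
          y = yi;
          have_f0 = false;
          ++n_accept;
          continue; // keep current h
        }
      }

      // plain accepted step: dense output on [t, t+h]
      while (out_idx < n_out && out_times[out_idx] <= t_acc + teps) {
        double to = out_times[out_idx];
        std::vector<double> yo(nw);
        hermite((to - t) / h, h, y.data(), f0.data(), ynew.data(),
                fnew.data(), n, yo.data());
        fill_row(out_idx, to, yo.data());
        ++out_idx;
      }
      t = t_acc;
      y = ynew;
      f0 = fnew;
      have_f0 = ros || KT.fsal;
      ++n_accept;
      double fac = (enorm == 0.0) ? 5.0
        : std::min(5.0, std::max(0.2, 0.9 * std::pow(enorm, -1.0 / order)));
      h *= fac;
      if (hmax > 0 && h > hmax) h = hmax;
    } else {
      double fac = std::min(5.0, std::max(0.2,
        0.9 * std::pow(std::max(enorm, 1e-10), -1.0 / order)));
      if (fac > 0.9) fac = 0.5;
      h *= fac;
    }
    if (h < hmin) { status = 1; t_fail = t; break; }
  }

  NumericVector yend(n);
  for (int i = 0; i < n; ++i) yend[i] = y[i];
  return List::create(_["out"] = out, _["status"] = status,
                      _["t_fail"] = t_fail, _["n_steps"] = steps,
                      _["n_accept"] = (double)n_accept,
                      _["n_eval"] = (double)f.n_eval,
                      _["y_end"] = yend, _["t_end"] = t);
}
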