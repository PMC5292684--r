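#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>

/* ---- transport-limited 1:1 binding model, deSolve compiled interface ----
 * parms: k_on, k_off, r_max, k_t, conc
 * dR/dt = [k_on C (Rmax - R) - k_off R] / [1 + k_on (Rmax - R)/k_t]
 */
static double spr_parms[5];

void spr_initmod(void (*odeparms)(int *, double *))
{
    int n = 5;
    odeparms(&n, spr_parms);
}

void spr_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double kon = spr_parms[0], koff = spr_parms[1], rmax = spr_parms[2],
           kt = spr_parms[3], conc = spr_parms[4];
    double R = y[0];
    double num = kon * conc * (rmax - R) - koff * R;
    double den = R_FINITE(kt) ? 1.0 + kon * (rmax - R) / kt : 1.0;
    ydot[0] = num / den;
}

/* ---- Metropolis sampler for cooperative decoration on a capsid lattice ----
 *
 * State: occupancy of nsites sites on each of ncaps capsids sharing one
 * finite pool of ligand. Configuration weight
 *   W = exp(-E) * v^F / F!,   E = dg*Nbound + eps*Npairs,
 * where F is the free-ligand count and v an activity volume. Exchange moves
 * (insert from / remove to the pool at a uniformly chosen site) with
 * Metropolis acceptance satisfy detailed balance for this weight.
 *
 * adj: flat adjacency, offsets (length nsites+1) into neighbour list.
 * Returns final per-capsid occupancy, the occupancy histogram accumulated
 * over post-burn-in sweeps, the per-sweep mean occupancy trajectory, and the
 * final free count.
 */
SEXP C_coop_mc(SEXP s_nsites, SEXP s_adj, SEXP s_offsets, SEXP s_ncaps,
               SEXP s_total, SEXP s_dg, SEXP s_eps, SEXP s_v,
               SEXP s_sweeps, SEXP s_burnin, SEXP s_sample_every)
{
    const int nsites = INTEGER(s_nsites)[0];
    const int *adj = INTEGER(s_adj);
    const int *off = INTEGER(s_offsets);
    const int ncaps = INTEGER(s_ncaps)[0];
    const double total = REAL(s_total)[0];
    const double dg = REAL(s_dg)[0];
    const double eps = REAL(s_eps)[0];
    const double v = REAL(s_v)[0];
    const int sweeps = INTEGER(s_sweeps)[0];
    const int burnin = INTEGER(s_burnin)[0];
    const int sample_every = INTEGER(s_sample_every)[0];

    int *occ = (int *) R_alloc((size_t) ncaps * nsites, sizeof(int));
    int *count = (int *) R_alloc(ncaps, sizeof(int));
    memset(occ, 0, (size_t) ncaps * nsites * sizeof(int));
    memset(count, 0, ncaps * sizeof(int));

    SEXP s_hist = PROTECT(allocVector(REALSXP, nsites + 1));
    SEXP s_traj = PROTECT(allocVector(REALSXP, sweeps));
    double *hist = REAL(s_hist);
    double *traj = REAL(s_traj);
    memset(hist, 0, (nsites + 1) * sizeof(double));

    double freeL = total; /* all ligand free initially */
    long bound = 0;
    const long moves_per_sweep = (long) ncaps * nsites;

    GetRNGstate();
    for (int sw = 0; sw < sweeps; sw++) {
        for (long m = 0; m < moves_per_sweep; m++) {
            int c = (int) (unif_rand() * ncaps);
            if (c >= ncaps) c = ncaps - 1;
            int s = (int) (unif_rand() * nsites);
            if (s >= nsites) s = nsites - 1;
            int *oc = occ + (size_t) c * nsites;
            int nocc = 0;
            for (int j = off[s]; j < off[s + 1]; j++)
                nocc += oc[adj[j]];
            if (oc[s]) { /* attempt removal to the pool */
                double a = exp(dg + eps * nocc) * v / (freeL + 1.0);
                if (a >= 1.0 || unif_rand() < a) {
                    oc[s] = 0; count[c]--; bound--; freeL += 1.0;
                }
            } else if (freeL >= 1.0) { /* attempt insertion from the pool */
                double a = exp(-(dg + eps * nocc)) * freeL / v;
                if (a >= 1.0 || unif_rand() < a) {
                    oc[s] = 1; count[c]++; bound++; freeL -= 1.0;
                }
            }
        }
        traj[sw] = (double) bound / ncaps;
        if (sw >= burnin && ((sw - burnin) % sample_every == 0))
            for (int c = 0; c < ncaps; c++)
                hist[count[c]] += 1.0;
        R_CheckUserInterrupt();
    }
    PutRNGstate();

    SEXP s_count = PROTECT(allocVector(INTSXP, ncaps));
    memcpy(INTEGER(s_count), count, ncaps * sizeof(int));
    SEXP s_free = PROTECT(ScalarReal(freeL));

    SEXP out = PROTECT(allocVector(VECSXP, 4));
    SET_VECTOR_ELT(out, 0, s_count);
    SET_VECTOR_ELT(out, 1, s_hist);
    SET_VECTOR_ELT(out, 2, s_traj);
    SET_VECTOR_ELT(out, 3, s_free);
    SEXP nm = PROTECT(allocVector(STRSXP, 4));
    SET_STRING_ELT(nm, 0, mkChar("count"));
    SET_STRING_ELT(nm, 1, mkChar("hist"));
    SET_STRING_ELT(nm, 2, mkChar("traj"));
    SET_STRING_ELT(nm, 3, mkChar("free"));
    setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(6);
    return out;
}
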