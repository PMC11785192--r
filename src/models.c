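/* Compiled right-hand sides for the tumor / CAR T / oncolytic virus ODE
 * models, in the calling convention expected by deSolve's lsoda().
 *
 * Parameter vector for the dimensional models (length 11, fixed order):
 *   0 alpha    tumor proliferation rate           1/h
 *   1 K        tumor carrying capacity            CI
 *   2 beta_TV  tumor infection rate               1/(MOI h)
 *   3 beta_CV  CAR T infection rate               1/(MOI h)
 *   4 theta_TC CAR T kill rate, tumor cells       1/(CI h)
 *   5 theta_IC CAR T kill rate, infected cells    1/(CI h)
 *   6 gamma    infected-cell lysis rate           1/h
 *   7 b        burst size                         MOI/CI
 *   8 omega    virus clearance rate               1/h
 *   9 delta    CAR T death rate                   1/h
 *  10 mu       CAR T expansion/exhaustion rate    1/(CI h)
 */
#include <R.h>

static double p[11];   /* dimensional models */
static double q[3];    /* scaled sub-modules */

void cartov_init11(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, p);
}

void cartov_init2(void (*odeparms)(int *, double *))
{
    int n = 2;
    odeparms(&n, q);
}

void cartov_init3(void (*odeparms)(int *, double *))
{
    int n = 3;
    odeparms(&n, q);
}

/* Full model: y = (T, I, V, C) */
void cartov_deriv_full(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double T = y[0], I = y[1], V = y[2], C = y[3];
    ydot[0] = p[0] * T * (1.0 - (T + I) / p[1]) - p[2] * T * V - p[4] * T * C;
    ydot[1] = p[2] * T * V - p[6] * I - p[5] * I * C;
    ydot[2] = p[6] * p[7] * I - p[8] * V;
    ydot[3] = -p[9] * C + p[10] * C * (T + I) - p[3] * C * V;
}

/* CAR T module: y = (T, C) */
void cartov_deriv_cart(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double T = y[0], C = y[1];
    ydot[0] = p[0] * T * (1.0 - T / p[1]) - p[4] * T * C;
    ydot[1] = -p[9] * C + p[10] * C * T;
}

/* OV module: y = (T, I, V) */
void cartov_deriv_ov(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double T = y[0], I = y[1], V = y[2];
    ydot[0] = p[0] * T * (1.0 - (T + I) / p[1]) - p[2] * T * V;
    ydot[1] = p[2] * T * V - p[6] * I;
    ydot[2] = p[6] * p[7] * I - p[8] * V;
}

/* Scaled CAR T module, q = (A, B): Y1' = Y1(1-Y1) - Y1 Y2,
 * Y2' = -A Y2 + B Y1 Y2 */
void cartov_deriv_cart_scaled(int *neq, double *t, double *y, double *ydot,
                              double *yout, int *ip)
{
    double y1 = y[0], y2 = y[1];
    ydot[0] = y1 * (1.0 - y1) - y1 * y2;
    ydot[1] = -q[0] * y2 + q[1] * y1 * y2;
}

/* Scaled OV module, q = (D, E, F): y1' = y1(1-y1-y2) - y1 y3,
 * y2' = y1 y3 - D y2, y3' = E y2 - F y3 */
void cartov_deriv_ov_scaled(int *neq, double *t, double *y, double *ydot,
                            double *yout, int *ip)
{
    double y1 = y[0], y2 = y[1], y3 = y[2];
    ydot[0] = y1 * (1.0 - y1 - y2) - y1 * y3;
    ydot[1] = y1 * y3 - q[0] * y2;
    ydot[2] = q[1] * y2 - q[2] * y3;
}
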