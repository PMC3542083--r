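label,kind,velocity,dynamic_viscosity,fluid_density,diffusion_coefficient,surface_diffusion,dc,pe_branch,re_branch,surface_area,volume,sv_ratio,sm_mag_mean
SIM_NO_FLOW,simulated,0,NA,NA,1,3.00e-4,2.42e-3,0,0,4.95e-2,1.19e-4,416,3.27e-3
SIM_FLOW_D1,simulated,0.05,5.00e-2,1.00e3,1.00e-1,3.00e-4,2.26e-3,1.13e-3,2.26,4.59e-2,1.12e-4,410,3.98e-3
SIM_FLOW_D2,simulated,0.05,5.00e-2,1.00e3,1.00e-2,3.00e-4,2.10e-3,1.05e-2,2.10,3.64e-2,8.98e-5,405,11.25e-3
SIM_FLOW_D3,simulated,0.05,5.00e-2,1.00e3,1.00e-3,3.00e-4,1.94e-3,9.7e-2,1.9,3.22e-2,7.74e-5,416,28.77e-3
SIM_FLOW_D4,simulated,0.05,5.00e-2,1.00e3,1.00e-4,3.00e-4,2.26e-3,1.13,2.26,2.30e-2,6.34e-5,363,33.45e-3
SIM_FLOW_D5,simulated,0.05,5.00e-2,1.00e3,1.00e-5,3.00e-4,NA,11,2,3.45e-2,1.03e-4,335,NA
CT_456,ct,0.05,1.00e-3,1.00e3,1.00e-3,NA,2.71e-3,1.36e-1,135.5,1.32e-1,1.53e-4,863,2.4e-3
TS_002,ct,0.01,1.00e-3,1.00e3,1.00e-3,NA,1.63e-3,1.63e-2,16.3,4.97e-2,8.46e-5,587,1.93e-3
TS_001,ct,0.15,1.00e-3,1.00e3,1.00e-3,NA,1.25e-3,1.88e-1,187.5,8.64e-2,1.28e-4,675,3.96e-3
TS_003,ct,0.15,1.00e-3,1.00e3,1.00e-3,NA,1.51e-3,2.27e-1,226.5,4.13e-2,7.15e-5,578,7.36e-3
CT_455,ct,0.15,1.00e-3,1.00e3,1.00e-3,NA,1.92e-3,2.88e-1,288,1.03e-1,1.38e-4,746,20.53e-3
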