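name,kind,density,sound_speed,compressibility,dynamic_viscosity,bulk_viscosity,poisson,diameter
water,fluid,997,1497,4.48e-10,0.00089,0.00247,NA,NA
polystyrene,particle,1050,2350,1.72e-10,NA,NA,0.35,NA
pdms,solid,920,1076.5,NA,NA,NA,NA,NA
linbo3_128yx,substrate,4650,3997,NA,NA,NA,NA,NA
wbc,cell,1019,NA,3.99e-10,NA,NA,NA,12e-6
mcf7,cell,1068,NA,4.22e-10,NA,NA,NA,20e-6
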